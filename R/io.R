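#' @importFrom utils write.table type.convert packageVersion
NULL

# write via a temp file in the target directory, then rename (atomic on
# POSIX filesystems)
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path)
  invisible(path)
}

#' Write a data frame as a metadata-headed TSV
#'
#' Dialect used by every stage: UTF-8, tab-separated, `#key=value`
#' metadata lines, a single column-name line, missing values as empty
#' strings.  Written atomically (temp file + rename).
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param meta Named list written as `#key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (k in names(meta))
      writeLines(sprintf("#%s=%s", k, format(meta[[k]])), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
  })
}

#' Read a metadata-headed TSV
#'
#' Strict counterpart of [write_tsv_meta()]: every data row must have
#' exactly as many fields as the header; violations are reported with
#' their file line number.
#'
#' @param path Input path.
#' @return data.frame (types auto-converted) with the `#` metadata in
#'   `attr(, "meta")`.
#' @export
read_tsv_meta <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  body_at <- which(!is_meta)
  if (!length(body_at)) stop("no header line in ", path)
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1,
                                                        nchar(kv))
  }
  header <- strsplit(lines[body_at[1L]], "\t", fixed = TRUE)[[1L]]
  rows <- body_at[-1L]
  # field count = tab count + 1 (robust to trailing empty fields, which
  # strsplit would silently drop)
  nf <- nchar(lines[rows]) -
    nchar(gsub("\t", "", lines[rows], fixed = TRUE)) + 1L
  bad <- which(nf != length(header))
  if (length(bad))
    stop(sprintf("malformed TSV %s at line %d: expected %d columns, found %d",
                 path, rows[bad[1L]], length(header), nf[bad[1L]]))
  fields <- lapply(strsplit(lines[rows], "\t", fixed = TRUE), function(f)
    c(f, rep("", length(header) - length(f))))
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  if (!nrow(df)) df <- as.data.frame(matrix(character(), ncol =
                                              length(header)))
  names(df) <- header
  df[] <- lapply(df, function(col) type.convert(col, as.is = TRUE))
  attr(df, "meta") <- meta
  df
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path; `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  atomic_write(path, function(tmp) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), tmp,
                                compress = grepl("\\.gz$", path))
  })
}

#' Read a FASTA file as a named character vector
#'
#' @param path Input path (optionally gzipped).
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write loci as BED (0-based, half-open)
#'
#' @param loci data.frame with columns `chrom`, `start`, `end`, `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(loci)))
  atomic_write(path, function(tmp)
    write.table(loci[, c("chrom", "start", "end", "name")], tmp,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE))
}

#' Read or write a YAML run configuration
#'
#' @param path YAML file path.
#' @return For `read_config`, the configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  yaml::read_yaml(path)
}

#' @param config Configuration list.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  atomic_write(path, function(tmp) yaml::write_yaml(config, tmp))
}

#' Write a machine-readable run manifest
#'
#' Records stage name, package version, RNG seed and kind, configuration,
#' and md5 checksums of the stage inputs, next to every stage output.
#'
#' @param path Output JSON path.
#' @param stage Stage name.
#' @param seed Integer seed used (or `NA`).
#' @param config Configuration list echoed into the manifest.
#' @param inputs Character vector of input paths to checksum.
#' @param outputs Character vector of paths written by the stage.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, seed = NA_integer_, config = list(),
                           inputs = character(), outputs = character()) {
  checksums <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(stage = stage,
                   package = "spikequant",
                   version = as.character(packageVersion("spikequant")),
                   r_version = as.character(getRversion()),
                   rng_kind = RNGkind()[1L], seed = seed,
                   config = config, input_md5 = checksums,
                   outputs = as.list(basename(outputs)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  atomic_write(path, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null"))
}
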