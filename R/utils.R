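#' @importFrom data.table data.table := as.data.table setorder setnames rbindlist fread dcast .N .SD
#' @importFrom stats rnbinom rbinom rpois rnorm runif t.test p.adjust pbinom dbinom binom.test
#'   hclust cutree as.dist cor sd setNames pnorm median
#' @importFrom utils combn head tail
#' @importFrom graphics hist
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as TSV with provenance header comments
#'
#' All tabular outputs of the pipeline carry `#`-prefixed header lines
#' recording the generating function, parameters and seed, followed by a
#' column-header line.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param comments character vector of comment lines (without leading `#`).
#' @return `path`, invisibly.
#' @export
write_tsv_c <- function(x, path, comments = character()) {
  lines <- character()
  if (length(comments)) lines <- paste0("# ", comments)
  lines <- c(lines, paste(names(x), collapse = "\t"))
  if (nrow(x)) {
    body <- do.call(paste, c(lapply(x, as.character), sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV written by [write_tsv_c()]
#'
#' Skips `#` comment lines and reads the header row.
#'
#' @param path file path.
#' @return data.table.
#' @export
read_tsv_c <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t", header = TRUE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Derive a deterministic sub-stream seed for one output file from the master
# seed; fixed offsets keep streams independent so adding one output never
# perturbs another. Kept below 2^31.
substream <- function(seed, offset) {
  (as.integer(seed) * 101L + as.integer(offset)) %% 2000000011L
}
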