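#' Derive a reproducible substream seed from a base seed and a key
#'
#' Stage- and signature-level randomness is driven by substreams of one global
#' seed so that adding a stage (or a signature) never perturbs the draws of the
#' others. The key is hashed with a small polynomial rolling hash and folded
#' into the base seed modulo 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param key Character scalar naming the substream (stage or signature name).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key), length(key) == 1L)
  m <- 2147483647
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% m
  as.integer(((seed %% m) + h * 2654435) %% m)
}

#' Stable hash of a configuration object
#'
#' Serialises the object to YAML and returns the MD5 of the serialisation, so
#' that every output file can record which configuration produced it.
#'
#' @param x A list-like configuration object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f), add = TRUE)
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

#' Write a data frame as CSV with a provenance comment header
#'
#' The header records the RNG seed and configuration hash as `#`-prefixed
#' comment lines, making any stochastic stage replayable. Timestamps are
#' deliberately not written so that reruns are bit-identical.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @param config_hash Optional configuration hash to record.
#' @return Invisibly, `path`.
#' @export
write_annotated_csv <- function(df, path, seed = NULL, config_hash = NULL) {
  stopifnot(is.data.frame(df))
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con), add = TRUE)
  if (!is.null(seed)) writeLines(paste0("# seed: ", format(seed, scientific = FALSE)), con)
  if (!is.null(config_hash)) writeLines(paste0("# config: ", config_hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE, qmethod = "double")
  invisible(path)
}

#' Read a CSV written by [write_annotated_csv()]
#'
#' @param path File path.
#' @return Data frame (comment header lines are skipped).
#' @export
read_annotated_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve of a score against a binary truth, computed from
#' the Mann-Whitney U statistic (ties shared equally).
#'
#' @param score Numeric score vector.
#' @param truth Logical vector, `TRUE` for positives.
#' @return AUC in `[0, 1]`, or `NA` if either class is empty.
#' @export
rank_auc <- function(score, truth) {
  stopifnot(length(score) == length(truth), is.logical(truth))
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
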