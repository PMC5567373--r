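#' @keywords internal
"_PACKAGE"

# Run code under a local RNG state seeded with `seed`, restoring the caller's
# state afterwards so library functions never disturb a user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# Deterministic TSV writer: fixed 15-significant-digit formatting so reruns
# with identical seeds produce byte-identical report files.
write_tsv_det <- function(df, path) {
  fmt <- function(col) {
    if (is.double(col)) {
      out <- ifelse(is.na(col), "NA", formatC(col, digits = 15, format = "g"))
      out
    } else if (is.logical(col)) {
      ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
    } else {
      out <- as.character(col)
      out[is.na(out)] <- "NA"
      out
    }
  }
  mat <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, names(df)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L)
    writeLines(apply(mat, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", comment.char = "", ...)
}
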