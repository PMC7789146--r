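# internal numerical helpers

the <- new.env(parent = emptyenv())

# Gauss-Hermite nodes/weights (physicists' convention), cached per order
gh_rule <- function(order) {
  key <- as.character(order)
  if (is.null(the$gh[[key]])) {
    if (is.null(the$gh)) the$gh <- list()
    the$gh[[key]] <- pracma::gaussHermite(order)
  }
  the$gh[[key]]
}

# row-wise log(sum(exp(x))) for a matrix, guarded against -Inf rows
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

# run `expr` under `seed` when given, without touching the caller's RNG state
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name, open0 = FALSE, open1 = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (open0 && x <= 0) || (!open0 && x < 0) ||
      (open1 && x >= 1) || (!open1 && x > 1)) {
    abort(sprintf("`%s` must be a single number in %s0, 1%s.",
                  name, if (open0) "(" else "[", if (open1) ")" else "]"))
  }
  invisible(x)
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(
    x,
    c("f", "female", "2", "v", "w") ~ "female",
    c("m", "male", "1") ~ "male",
    .default = NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(sprintf("Unrecognized sex code(s): %s.",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  out
}
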