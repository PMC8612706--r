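# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Standard deviation under a stated convention. "sample" is the package-wide
# default (n-1 denominator); "population" divides by n.
.sd_conv <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  s
}

# Coefficient of variation, sd/mean.
.cv <- function(x, sd_type = "sample") {
  m <- mean(x)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  .sd_conv(x, sd_type) / m
}

# Clip correlations away from +-1 before Fisher transformation.
.clip_r <- function(r, limit = 0.999999) {
  hit <- is.finite(r) & abs(r) >= 1
  if (any(hit)) {
    warning("correlations at +-1 clipped to +-", limit, " before Fisher averaging")
    r[hit] <- sign(r[hit]) * limit
  }
  r
}

# Evaluate an arithmetic expression string over feature columns of `data`.
# Only the five feature symbols and basic arithmetic are permitted.
.eval_feature_expr <- function(expr, data) {
  e <- str2lang(expr)
  allowed <- c("CS", "CI", "CII", "CIV", "mtDNAcn", "+", "-", "*", "/", "(")
  syms <- all.names(e)
  bad <- setdiff(syms, allowed)
  assert_that(length(bad) == 0,
              paste0("expression '", expr, "' uses undefined symbols: ",
                     paste(bad, collapse = ", ")))
  eval(e, envir = data, enclos = baseenv())
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators do not perturb user RNG flow.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.feature_names <- c("CS", "CI", "CII", "CIV", "mtDNAcn")
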