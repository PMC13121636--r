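## small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(1, pmax(0, x))

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (alphabet ACGT).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Beta-binomial random deviates
#'
#' Draws from a beta-binomial with mean `prob` and dispersion `phi`, where
#' `phi = 1 / (alpha + beta + 1)` is the intra-class correlation of the
#' underlying Beta. `phi = 0` reduces to the binomial.
#'
#' @param n number of deviates.
#' @param size binomial sizes (recycled).
#' @param prob mean success probability (recycled).
#' @param phi dispersion in `[0, 1)`.
#' @return integer vector of counts.
#' @export
rbetabinom <- function(n, size, prob, phi = 0) {
  stopifnot(phi >= 0, phi < 1)
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  if (phi == 0) return(rbinom(n, size, prob))
  theta <- (1 - phi) / phi           # alpha + beta
  p <- rbeta(n, prob * theta, (1 - prob) * theta)
  rbinom(n, size, p)
}

## log beta-binomial pmf with mean pi and concentration theta = alpha + beta
dbetabinom_log <- function(a, n, pi, theta) {
  al <- pi * theta
  be <- (1 - pi) * theta
  lchoose(n, a) + lbeta(a + al, n - a + be) - lbeta(al, be)
}

## composite site key used wherever sites are matched across tables
site_key <- function(contig, pos0, strand) {
  paste(contig, pos0, strand, sep = ":")
}

stop_glorid <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "glorid_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop_glorid(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")),
                "glorid_input_error")
  invisible(df)
}
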