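#' Round half-up to a fixed number of decimals
#'
#' Report tables round 0.005 upward (half-up), unlike [base::round()]'s
#' round-half-even. Used for percentage columns in QC reports; full
#' precision is always retained internally.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL draws one from entropy and logs it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message("relicdx: no seed supplied, using seed ", seed)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single probability in [0, 1], got %s",
          name, paste(format(x), collapse = ","))
  invisible(x)
}

# Coerce a reference to a named character vector of chromosome sequences.
as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else if (is.character(reference)) {
    out <- reference
    if (is.null(names(out)) && length(out) == 1L) names(out) <- "chr1"
  } else {
    stopf("reference must be a DNAStringSet or named character vector")
  }
  if (length(out) == 0L || any(nchar(out) == 0L))
    stopf("reference is empty")
  out
}
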