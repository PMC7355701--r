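# shared internal helpers

.Z95 <- 1.959964  # two-sided 95% normal quantile

expit <- function(x) 1 / (1 + exp(-x))

# upper-tail chi-square p from an LRT statistic; clamps tiny negative
# statistics produced by IRLS round-off to zero
.lrt_p <- function(stat, df) {
  if (is.na(stat) || is.na(df) || df <= 0) return(NA_real_)
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

# deviance-based log-likelihood difference of two nested glm fits
.lrt_stat <- function(fit_full, fit_reduced) {
  as.numeric(fit_reduced$deviance - fit_full$deviance)
}

# run code with the global RNG seeded, restoring prior RNG state afterwards
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# deterministic child seed for sub-analyses, kept inside 32-bit range
.child_seed <- function(master, index) {
  as.integer((as.double(master) * 1009 + 7919 * index) %% 2147483647L)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
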