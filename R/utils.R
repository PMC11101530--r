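## internal helpers shared across modules

# run 'expr' under a temporary RNG state seeded with 'seed', restoring the
# caller's stream afterwards; all generator determinism flows through this
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a per-stage child seed from a base seed, kept within 32-bit range
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + as.integer(stage) * 1009L) %% 2147483123L
}

# classic histogram Otsu threshold (256 bins over the data range); returns
# NA for a degenerate (constant) input
otsu_threshold <- function(v, nbins = 256L) {
  r <- range(v)
  if (!all(is.finite(r)) || diff(r) < 1e-12) {
    return(NA_real_)
  }
  bin <- pmin(nbins - 1L, as.integer((v - r[1]) / diff(r) * nbins))
  h <- tabulate(bin + 1L, nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- w0 * (1 - w0)
  sigma_b <- ifelse(denom > 0, (mu_t * w0 - mu)^2 / denom, -Inf)
  k <- which.max(sigma_b[-nbins])
  r[1] + k / nbins * diff(r)
}

stop_if_not_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf(
      "'%s' must be %s %s", name, if (strict) ">" else ">=", lower
    ), call. = FALSE)
  }
  invisible(x)
}
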