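# Internal helpers shared across modules.

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Check a scalar probability.
#' @noRd
.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopf("'%s' must be a single probability in [0, 1]", name)
  invisible(x)
}

#' @noRd
.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    .stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# Deterministic 31-bit sub-seed keyed by (seed, id). One RNG stream per
# sample: adding samples never perturbs existing ones.
#' @noRd
.derive_seed <- function(seed, id) {
  h <- 0
  for (b in utf8ToInt(as.character(id))) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# Truncated normal on [0, Inf), rounded to integer tail lengths.
# 'mean' may be a vector recycled to length n.
#' @noRd
.rtail <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  if (sd == 0) return(as.integer(round(pmax(mean, 0))))
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean[bad], sd)
    bad <- bad[out[bad] < 0]
  }
  as.integer(round(out))
}

# Reverse complement of plain character DNA (vectorised).
#' @noRd
.revcomp <- function(x) {
  comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' @noRd
.complement <- function(x) chartr("ACGTUacgtu", "TGCAAtgcaa", x)

# Benjamini-Hochberg wrapper kept for readability at call sites.
#' @noRd
.bh <- function(p) p.adjust(p, method = "BH")
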