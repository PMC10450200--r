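# Shared fixtures, built in code. All simulations are seeded; helpers keep
# the stated-world parameters (3v3 design, PAT-Seq-like tail scales) in one
# place.

design_3v3 <- function() {
  data.frame(sample_id = c(paste0("ctl", 1:3), paste0("dif", 1:3)),
             condition = rep(c("control", "differentiated"), each = 3),
             stringsAsFactors = FALSE)
}

# Sample sheet for read simulation on top of design_3v3().
sample_sheet <- function(tail_mean = c(44, 48), tail_sd = 15,
                         distal_usage = c(0.3, 0.5), depth = 50) {
  d <- design_3v3()
  d$tail_mean <- rep(tail_mean, each = 3)
  d$tail_sd <- tail_sd
  d$distal_usage <- rep(distal_usage, each = 3)
  d$depth <- depth
  d
}

# Brute-force two-sample KS D: max ECDF gap over the pooled values.
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# Brute-force seed-site oracle: checks every window of the UTR for a core
# match and classifies by flanks, independently of find_seed_sites().
brute_seed_sites <- function(utr, mirna) {
  utr <- chartr("Uu", "Tt", toupper(utr))
  mir <- chartr("Uu", "Tt", toupper(mirna))
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "",
                                       fixed = TRUE)[[1]]), collapse = "")
  core <- rc(substr(mir, 2, 7))
  m8 <- chartr("ACGT", "TGCA", substr(mir, 8, 8))
  n <- nchar(utr)
  out <- list()
  if (n < 6) return(data.frame(site_type = character(),
                               core_position = integer()))
  for (s in seq_len(n - 5)) {
    if (substr(utr, s, s + 5) != core) next
    has_m8 <- s > 1 && substr(utr, s - 1, s - 1) == m8
    has_a1 <- s + 6 <= n && substr(utr, s + 6, s + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    out[[length(out) + 1]] <- data.frame(site_type = type,
                                         core_position = s - 1L,
                                         stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(site_type = character(),
                                      core_position = integer()))
  do.call(rbind, out)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
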