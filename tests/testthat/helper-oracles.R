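# Independent oracles. These deliberately re-state the published
# nearest-neighbor constants and use naive algorithms (plain lookups,
# exhaustive enumeration, O(n^2) scans) so they share no code path with
# the package implementation they check.

ORACLE_DH <- c(
  AA = -7.6, TT = -7.6, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
ORACLE_DS <- c(
  AA = -21.3, TT = -21.3, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
ORACLE_INIT <- c(dh = 0.2, ds = -5.7)
ORACLE_TERM_AT <- c(dh = 2.2, ds = 6.9)

# hand-summed duplex free energy of a fully paired helix whose top strand
# reads `top`
oracle_duplex_dg <- function(top, temperature = 310.15, salt = 0.15) {
  n <- nchar(top)
  b <- strsplit(top, "")[[1]]
  dh <- ORACLE_INIT[["dh"]]
  ds <- ORACLE_INIT[["ds"]]
  for (i in seq_len(n - 1)) {
    step <- paste0(b[i], b[i + 1])
    dh <- dh + ORACLE_DH[[step]]
    ds <- ds + ORACLE_DS[[step]]
  }
  for (end in c(b[1], b[n])) {
    if (end %in% c("A", "T")) {
      dh <- dh + ORACLE_TERM_AT[["dh"]]
      ds <- ds + ORACLE_TERM_AT[["ds"]]
    }
  }
  ds <- ds + 0.368 * (n - 1) * log(salt)
  dh - temperature * ds / 1000
}

oracle_loop_table <- c(
  "3" = 3.5, "4" = 3.5, "5" = 3.3, "6" = 4.0, "7" = 4.2, "8" = 4.3,
  "9" = 4.5, "10" = 4.6, "11" = 4.8, "12" = 5.0, "13" = 5.05, "14" = 5.1,
  "15" = 5.2, "16" = 5.3, "17" = 5.4, "18" = 5.5, "19" = 5.6, "20" = 5.7,
  "21" = 5.78, "22" = 5.86, "23" = 5.94, "24" = 6.02, "25" = 6.1,
  "26" = 6.14, "27" = 6.18, "28" = 6.22, "29" = 6.26, "30" = 6.3
)

oracle_loop_penalty <- function(size, temperature = 310.15) {
  dg37 <- if (size <= 30) {
    oracle_loop_table[[as.character(size)]]
  } else {
    6.3 + 1.75 * 0.0019872 * 310.15 * log(size / 30)
  }
  dg37 * temperature / 310.15
}

# exhaustive hairpin enumeration: every (stem start, loop, stem length)
# placement with contiguous Watson-Crick stems >= 2 bp and loops >= 3 nt
oracle_hairpin_mfe <- function(seq, temperature = 310.15, salt = 0.15) {
  b <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  best <- Inf
  if (n < 7) {
    return(best)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in 2:floor(n / 2)) {
        # stem arms b[i..i+k-1] and b[j..j+k-1], loop between them
        if (i + k - 1 > n || j + k - 1 > n) next
        loop <- j - (i + k)
        if (loop < 3) next
        ok <- TRUE
        for (t in 0:(k - 1)) {
          if (comp[[b[i + t]]] != b[j + k - 1 - t]) {
            ok <- FALSE
            break
          }
        }
        if (!ok) next
        stem_top <- paste(b[i:(i + k - 1)], collapse = "")
        dg <- oracle_duplex_dg(stem_top, temperature, salt) +
          oracle_loop_penalty(loop, temperature)
        best <- min(best, dg)
      }
    }
  }
  best
}

# brute-force longest antiparallel complementary run: scan every pair of
# end positions
oracle_cross_run <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      # run starting at a[i] (ascending) paired with b[j] (descending)
      k <- 0
      while (i + k <= length(av) && j - k >= 1 &&
        comp[[av[i + k]]] == bv[j - k]) {
        k <- k + 1
      }
      best <- max(best, k)
    }
  }
  best
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
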