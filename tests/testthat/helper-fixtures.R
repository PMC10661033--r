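# Fixtures are built in code: small references with a known coding-strand
# PAM, plus independent brute-force oracles used to cross-check the
# implementation (kept deliberately naive and separate from package code).

fixture_reference <- function(len = 400, pam3 = 200, seed = 99, gc = 0.45, ...) {
  set.seed(seed)
  random_amplicon(len, gc = gc, pam3_pos = pam3, ...)
}

fixture_guide <- function(ref, pam3 = 200) {
  g <- find_protospacers(ref)
  g <- g[g$strand == "coding" & g$pam3_pos == pam3, ]
  stopifnot(nrow(g) == 1)
  g$name <- "g1"
  g
}

q30 <- function(n) strrep("?", n)

# ---- brute-force glocal affine DP oracle -----------------------------------
# read global, reference local; gap of length L costs open + L * ext
# (penalties positive). Returns the optimal score only.
oracle_glocal_score <- function(read, ref, match = 1, mismatch = -1,
                                open = 4, ext = 1) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  m <- length(r); n <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)  # read base against a gap
  Iy <- matrix(NEG, m + 1, n + 1)  # ref base against a gap
  M[1, ] <- 0                       # free reference prefix
  for (i in 1:m) {
    for (j in 0:n) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext), Ix[i, j + 1] - ext)
      if (j >= 1) {
        sc <- if (r[i] == "N" || s[j] == "N") 0 else
          if (r[i] == s[j]) match else mismatch
        M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sc
        Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext), Iy[i + 1, j] - ext)
      }
    }
  }
  max(M[m + 1, ], Ix[m + 1, ], Iy[m + 1, ])
}

# ---- brute-force pileup recount --------------------------------------------
# loops over reads and columns; mirrors the stated counting rules only
oracle_pileup <- function(alignments, ref) {
  n <- nchar(ref$sequence)
  depth <- integer(n); indel <- integer(n)
  alt <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (k in seq_len(nrow(alignments))) {
    if (!alignments$aligned[k]) next
    cov <- alignments$ref_start[k]:alignments$ref_end[k]
    bad <- integer(0)
    ind <- alignments$indels[[k]]
    if (nrow(ind)) {
      for (r in seq_len(nrow(ind))) {
        if (ind$kind[r] == "deletion") {
          bad <- c(bad, ind$pos[r]:(ind$pos[r] + ind$length[r] - 1L))
        } else {
          bad <- c(bad, ind$pos[r])
        }
      }
    }
    bad <- unique(bad[bad >= 1])
    amb <- alignments$ambiguous[[k]]
    for (p in cov) {
      if (p %in% bad) indel[p] <- indel[p] + 1L
      else if (!(p %in% amb)) depth[p] <- depth[p] + 1L
    }
    mm <- alignments$mismatches[[k]]
    if (nrow(mm)) for (r in seq_len(nrow(mm))) {
      alt[mm$pos[r], mm$alt[r]] <- alt[mm$pos[r], mm$alt[r]] + 1L
    }
  }
  list(depth_clean = depth, alt = alt, indel_count = indel)
}

# ---- exhaustive window-extent search ---------------------------------------
oracle_extent <- function(rel_pos, rate, frac) {
  total <- sum(rate)
  best <- NULL
  n <- length(rel_pos)
  for (i in 1:n) for (j in i:n) {
    if (sum(rate[i:j]) >= frac * total - 1e-12) {
      width <- rel_pos[j] - rel_pos[i] + 1L
      mid <- abs((rel_pos[i] + rel_pos[j]) / 2)
      cand <- c(width, mid, rel_pos[i])
      if (is.null(best) || cand[1] < best[1] ||
          (cand[1] == best[1] && (cand[2] < best[2] ||
                                  (cand[2] == best[2] && cand[3] < best[3])))) {
        best <- cand
      }
    }
  }
  as.integer(best[1])
}

# random alignment-shaped reads for fuzzing: substring of the reference with
# optional substitutions and a deletion
random_read <- function(ref_seq, len, n_sub = 0, del = FALSE) {
  n <- nchar(ref_seq)
  start <- sample(n - len + 1L, 1)
  chars <- strsplit(substr(ref_seq, start, start + len - 1L), "")[[1]]
  if (n_sub > 0) {
    at <- sample(length(chars), n_sub)
    for (i in at) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  if (del) chars <- chars[-sample(2:(length(chars) - 1L), 1)]
  paste(chars, collapse = "")
}
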