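# Forward simulator of guide-directed cytidine-deaminase mutagenesis.
#
# Generative model: each site i of the amplicon has a per-generation
# substitution probability
#
#   q_i = r * w(d_i) * m(context_i) * s(base_i),   clamped to [0, 1]
#
# where r is the base per-site per-generation rate, w(d) a positional weight
# of the PAM-relative distance d (the smallest-|d| guide wins when several
# guides overlap, i.e. w is the maximum over guides), m a motif-context
# multiplier for cytosines (AGCT core > other WRCY > non-motif, evaluated on
# the strand carrying the C) and s a reference-base multiplier distinguishing
# C:G targets from the A:T background. After g generations (fractional
# allowed) the cumulative per-site mutated fraction is
#
#   p_i = 1 - (1 - q_i)^g
#
# and each genome carries at most one substitution per site (no
# back-mutation). Alternative bases are drawn from a per-reference-base
# outcome spectrum (C:G-biased by default). Sites where w = 0 never mutate;
# with the default uniform window this confines all signal, including the
# s(A/T)-scaled background, to the guide windows.

#' Default substitution outcome spectrum
#'
#' Row-stochastic 4x4 matrix of P(alt | ref) with a zero diagonal. The C row
#' is C->G-biased (G 0.5, T 0.35, A 0.15) as appropriate for a diversifying
#' cytidine base editor; the G row mirrors it by complement; A and T rows are
#' uniform (background events).
#'
#' @return A 4x4 numeric matrix with rownames/colnames A, C, G, T.
#' @export
default_spectrum <- function() {
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  m["C", c("A", "G", "T")] <- c(0.15, 0.50, 0.35)
  m["G", c("T", "C", "A")] <- c(0.15, 0.50, 0.35)  # complement mirror of the C row
  m["A", c("C", "G", "T")] <- 1 / 3
  m["T", c("A", "C", "G")] <- 1 / 3
  m
}

#' Build a simulation configuration
#'
#' Collects and validates every parameter of the deaminase mutagenesis
#' generative model (see the package vignette for the model itself).
#'
#' @param reference A `reference_amplicon` (or DNA string).
#' @param guides Guide tibble ([guide_design()]); may have zero rows, in
#'   which case no site has positional weight and nothing mutates.
#' @param base_rate Per-site per-generation substitution probability r.
#' @param window_halfwidth Half-width W of the positional window, bp.
#' @param window_shape `"uniform"` (w = 1 for |d| <= W, else 0),
#'   `"triangular"` (w = max(0, 1 - |d|/W)) or `"gaussian"`
#'   (w = exp(-d^2 / (2 (W/2)^2)), untruncated).
#' @param motif_multiplier Named numeric vector with entries `agct`, `wrcy`,
#'   `other`: context multipliers m applied to C:G sites.
#' @param base_multiplier Named numeric vector with entries `cg` and `at`:
#'   reference-base multipliers s; the `at` entry models the untargeted
#'   background at A:T pairs.
#' @param spectrum Row-stochastic 4x4 outcome matrix (see
#'   [default_spectrum()]).
#' @param generations Number of generations g (real, fractional allowed).
#' @param n_genomes Number of genomes in the simulated population.
#' @param read_length Read length for [sample_reads()].
#' @param paired Whether reads are paired-end.
#' @param seq_error_rate Per-base sequencing substitution-error probability.
#' @param indel_rate Per-site per-genome single-base deletion probability.
#' @param seed Integer master seed for the genome-drawing stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(reference, guides,
                              base_rate = 2.13e-4,
                              window_halfwidth = 50L,
                              window_shape = c("uniform", "triangular", "gaussian"),
                              motif_multiplier = c(agct = 1, wrcy = 1, other = 1),
                              base_multiplier = c(cg = 1, at = 1),
                              spectrum = default_spectrum(),
                              generations = 20.5,
                              n_genomes = 1000L,
                              read_length = 250L,
                              paired = TRUE,
                              seq_error_rate = 0,
                              indel_rate = 0,
                              seed = 1L) {
  reference <- as_reference(reference)
  window_shape <- match.arg(window_shape)
  guides <- as_tibble(guides)
  if (nrow(guides) > 0L) validate_guides(guides, reference)
  if (!is_prob(base_rate)) abort("`base_rate` must be a probability in [0, 1].")
  if (!is_prob(seq_error_rate)) abort("`seq_error_rate` must be in [0, 1].")
  if (!is_prob(indel_rate)) abort("`indel_rate` must be in [0, 1].")
  stopifnot(window_halfwidth >= 0, generations >= 0,
            n_genomes >= 1, read_length >= 1)
  for (nm in c("agct", "wrcy", "other")) {
    if (is.na(motif_multiplier[nm]) || motif_multiplier[nm] < 0) {
      abort("`motif_multiplier` needs non-negative entries agct, wrcy, other.")
    }
  }
  for (nm in c("cg", "at")) {
    if (is.na(base_multiplier[nm]) || base_multiplier[nm] < 0) {
      abort("`base_multiplier` needs non-negative entries cg, at.")
    }
  }
  spectrum <- as.matrix(spectrum)
  stopifnot(identical(dim(spectrum), c(4L, 4L)),
            identical(rownames(spectrum), DNA_BASES),
            identical(colnames(spectrum), DNA_BASES))
  if (any(diag(spectrum) != 0) || any(spectrum < 0)) {
    abort("`spectrum` must be non-negative with a zero diagonal.")
  }
  if (any(abs(rowSums(spectrum) - 1) > 1e-12)) {
    abort("`spectrum` rows must each sum to 1 (within 1e-12).")
  }
  structure(
    list(reference = reference, guides = guides, base_rate = base_rate,
         window_halfwidth = as.numeric(window_halfwidth),
         window_shape = window_shape,
         motif_multiplier = motif_multiplier, base_multiplier = base_multiplier,
         spectrum = spectrum, generations = generations,
         n_genomes = as.integer(n_genomes), read_length = as.integer(read_length),
         paired = isTRUE(paired), seq_error_rate = seq_error_rate,
         indel_rate = indel_rate, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> %d genomes of %s (%d bp), %d guide(s)\n",
                     "  r = %.3g /site/generation, g = %.3g, %s window W = %g bp\n"),
              x$n_genomes, x$reference$id, x$reference$length, nrow(x$guides),
              x$base_rate, x$generations, x$window_shape, x$window_halfwidth))
  invisible(x)
}

# positional weight of PAM-relative distance d
window_weight <- function(d, halfwidth, shape) {
  switch(shape,
    uniform = as.numeric(abs(d) <= halfwidth),
    triangular = pmax(0, 1 - abs(d) / halfwidth),
    gaussian = exp(-d^2 / (2 * (halfwidth / 2)^2))
  )
}

# PAM-relative coordinate of coding positions for one guide:
# 0 at the PAM 3' end, sign following the protospacer strand's 5'->3'.
pam_relative <- function(pos, strand, pam3_pos) {
  if (strand == "coding") pos - pam3_pos else pam3_pos - pos
}

# classify cytosine motif context for every site; non-C:G sites and sites too
# close to an edge are "other" (non-motif)
classify_context <- function(sequence) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  ctx <- rep("other", n)
  is_w <- chars %in% c("A", "T")
  is_r <- chars %in% c("A", "G")
  is_y <- chars %in% c("C", "T")
  # C on the coding strand: 4-mer chars[i-2..i+1] must be W R C Y
  idx <- which(chars == "C")
  idx <- idx[idx >= 3L & idx <= n - 1L]
  if (length(idx)) {
    wrcy <- is_w[idx - 2L] & is_r[idx - 1L] & is_y[idx + 1L]
    agct <- chars[idx - 2L] == "A" & chars[idx - 1L] == "G" & chars[idx + 1L] == "T"
    ctx[idx[wrcy]] <- "wrcy"
    ctx[idx[agct & wrcy]] <- "agct"
  }
  # G on the coding strand: the C sits on the template; its 4-mer is the
  # reverse complement of chars[i-1..i+2]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  idx <- which(chars == "G")
  idx <- idx[idx >= 2L & idx <= n - 2L]
  if (length(idx)) {
    tw <- comp[chars[idx + 2L]] %in% c("A", "T")
    tr <- comp[chars[idx + 1L]] %in% c("A", "G")
    ty <- comp[chars[idx - 1L]] %in% c("C", "T")
    wrcy <- tw & tr & ty
    agct <- comp[chars[idx + 2L]] == "A" & comp[chars[idx + 1L]] == "G" &
      comp[chars[idx - 1L]] == "T"
    ctx[idx[wrcy]] <- "wrcy"
    ctx[idx[agct & wrcy]] <- "agct"
  }
  ctx
}

#' Per-site mutation probabilities under a configuration
#'
#' Closed-form per-site per-generation probability q and cumulative mutated
#' fraction p = 1 - (1 - q)^g for every reference position. A configuration
#' warning is recorded (via `warning()`) when any q exceeds 1 before
#' clamping.
#'
#' @param config A `simulation_config`.
#' @return Tibble with `pos`, `ref`, `context`, `weight`, `q`, `p`.
#' @export
site_mutation_rates <- function(config) {
  ref <- config$reference
  chars <- seq_chars(ref$sequence)
  n <- ref$length
  pos <- seq_len(n)
  w <- rep(0, n)
  if (nrow(config$guides) > 0L) {
    for (i in seq_len(nrow(config$guides))) {
      d <- pam_relative(pos, config$guides$strand[i], config$guides$pam3_pos[i])
      w <- pmax(w, window_weight(d, config$window_halfwidth, config$window_shape))
    }
  }
  ctx <- classify_context(ref$sequence)
  m <- unname(config$motif_multiplier[c(agct = "agct", wrcy = "wrcy", other = "other")[ctx]])
  s <- if_else(chars %in% c("C", "G"),
               unname(config$base_multiplier["cg"]),
               unname(config$base_multiplier["at"]))
  q <- config$base_rate * w * m * s
  if (any(q > 1)) {
    warn(sprintf("%d site(s) had q > 1 before clamping; check the configuration.",
                 sum(q > 1)))
    q <- pmin(q, 1)
  }
  p <- 1 - (1 - q)^config$generations
  tibble(pos = pos, ref = chars, context = ctx, weight = w, q = q, p = p)
}

#' Simulate a mutagenized genome population
#'
#' Draws `n_genomes` amplicon copies under the deaminase model (see
#' [simulation_config()]): each site of each genome mutates independently
#' with its closed-form cumulative probability p, alternative bases follow
#' the configured outcome spectrum, and (optionally) single-base deletions
#' occur at `indel_rate`. Deterministic for a fixed `config$seed`; the seed
#' consumed here is independent of the one used by [sample_reads()], so
#' changing the read sample never perturbs the genome draws.
#'
#' @param config A `simulation_config`.
#' @return An object of class `genome_pool`: list with `sequences`
#'   (character vector of length `n_genomes`), `mutations` (tibble `genome`,
#'   `pos`, `ref`, `alt`), `deletions` (tibble `genome`, `pos`), `site_rates`
#'   (the [site_mutation_rates()] table) and `config`.
#' @export
simulate_mutagenesis <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rates <- site_mutation_rates(config)
  ng <- config$n_genomes
  set.seed(config$seed)
  active <- which(rates$p > 0)
  muts <- vector("list", length(active))
  for (k in seq_along(active)) {
    i <- active[k]
    hit <- which(runif(ng) < rates$p[i])
    if (length(hit)) {
      muts[[k]] <- tibble(genome = hit, pos = rates$pos[i], ref = rates$ref[i],
                          alt = draw_alt_bases(rates$ref[i], length(hit),
                                               config$spectrum))
    }
  }
  mutations <- if (length(muts)) bind_rows(muts) else
    tibble(genome = integer(), pos = integer(), ref = character(), alt = character())
  mutations <- arrange(mutations, .data$genome, .data$pos)

  deletions <- tibble(genome = integer(), pos = integer())
  if (config$indel_rate > 0) {
    n <- config$reference$length
    dels <- vector("list", n)
    for (i in seq_len(n)) {
      hit <- which(runif(ng) < config$indel_rate)
      if (length(hit)) dels[[i]] <- tibble(genome = hit, pos = i)
    }
    dels <- purrr::compact(dels)
    if (length(dels)) deletions <- arrange(bind_rows(dels), .data$genome, .data$pos)
  }

  sequences <- rep(config$reference$sequence, ng)
  touched <- sort(unique(c(mutations$genome, deletions$genome)))
  if (length(touched)) {
    mut_by_g <- split(mutations, mutations$genome)
    del_by_g <- split(deletions, deletions$genome)
    base_chars <- seq_chars(config$reference$sequence)
    for (g in touched) {
      chars <- base_chars
      mg <- mut_by_g[[as.character(g)]]
      if (!is.null(mg)) chars[mg$pos] <- mg$alt
      dg <- del_by_g[[as.character(g)]]
      if (!is.null(dg)) chars <- chars[-dg$pos]
      sequences[g] <- paste(chars, collapse = "")
    }
  }
  structure(
    list(sequences = sequences, mutations = mutations, deletions = deletions,
         site_rates = rates, config = config),
    class = "genome_pool"
  )
}

#' @export
print.genome_pool <- function(x, ...) {
  cat(sprintf("<genome_pool> %d genomes, %d substitutions, %d deletions\n",
              length(x$sequences), nrow(x$mutations), nrow(x$deletions)))
  invisible(x)
}

#' Fraction of genomes carrying a target codon
#'
#' The fluorescence-shift observable: the fraction of genomes whose codon at
#' `codon_index` (counting from the reference's `orf_start`) equals
#' `target_codon` exactly — for example the S65T codon conversion that turns
#' wtGFP into eGFP. Codons are evaluated on reference coordinates with each
#' genome's substitutions applied; a genome with a deletion inside the codon
#' never matches.
#'
#' @param pool A `genome_pool`.
#' @param codon_index 1-based codon index within the ORF.
#' @param target_codon DNA triplet to match.
#' @return A single fraction in \[0, 1\].
#' @export
egfp_shift_fraction <- function(pool, codon_index, target_codon) {
  stopifnot(inherits(pool, "genome_pool"))
  ref <- pool$config$reference
  if (is.null(ref$orf_start)) abort("reference has no `orf_start`.")
  target_codon <- toupper(target_codon)
  if (!grepl("^[ACGT]{3}$", target_codon)) abort("`target_codon` must be a DNA triplet.")
  cstart <- ref$orf_start + 3L * (as.integer(codon_index) - 1L)
  if (codon_index < 1L || cstart + 2L > ref$length) {
    abort("`codon_index` outside the reference ORF.")
  }
  cpos <- cstart:(cstart + 2L)
  ref_codon <- substr(ref$sequence, cstart, cstart + 2L)
  ng <- length(pool$sequences)
  codons <- rep(ref_codon, ng)
  in_codon <- filter(pool$mutations, .data$pos %in% cpos)
  if (nrow(in_codon)) {
    for (g in unique(in_codon$genome)) {
      mg <- in_codon[in_codon$genome == g, ]
      chars <- seq_chars(ref_codon)
      chars[mg$pos - cstart + 1L] <- mg$alt
      codons[g] <- paste(chars, collapse = "")
    }
  }
  hit <- codons == target_codon
  if (nrow(pool$deletions)) {
    del_in <- unique(pool$deletions$genome[pool$deletions$pos %in% cpos])
    hit[del_in] <- FALSE
  }
  mean(hit)
}

#' Expected window-mean substitution fraction
#'
#' Closed-form expectation of the per-site mutated fraction averaged over the
#' positions within `halfwidth` of `center` — the quantity the sequencing
#' pipeline estimates as the window-mean substitution frequency.
#'
#' @param config A `simulation_config`.
#' @param center 1-based reference position (defaults to the first guide's
#'   PAM 3' end).
#' @param halfwidth Window half-width in bp (defaults to the configuration's).
#' @return A single expected rate.
#' @export
expected_window_mean <- function(config, center = NULL, halfwidth = NULL) {
  rates <- site_mutation_rates(config)
  if (is.null(center)) center <- config$guides$pam3_pos[1]
  if (is.null(halfwidth)) halfwidth <- config$window_halfwidth
  sel <- rates$pos >= center - halfwidth & rates$pos <= center + halfwidth
  mean(rates$p[sel])
}

#' Calibrate the A:T background multiplier to a target spectrum share
#'
#' Solves for the `base_multiplier["at"]` value at which the closed-form
#' expected share of substitutions occurring at A or T reference bases —
#' within `halfwidth` of `center` — equals `target_share`, given the
#' reference's base composition there. Used to emulate a measured A/T
#' fraction (for example 1.3% of all substitutions).
#'
#' @param config A `simulation_config` (its current `at` entry is ignored).
#' @param target_share Desired expected A/T share of substitutions, in
#'   \[0, 1).
#' @param center,halfwidth Window definition as in [expected_window_mean()].
#' @return The calibrated `at` multiplier (scalar).
#' @export
calibrate_at_multiplier <- function(config, target_share, center = NULL,
                                    halfwidth = NULL) {
  stopifnot(target_share >= 0, target_share < 1)
  if (is.null(center)) center <- config$guides$pam3_pos[1]
  if (is.null(halfwidth)) halfwidth <- config$window_halfwidth
  share_at <- function(s_at) {
    cfg <- config
    cfg$base_multiplier["at"] <- s_at
    rates <- site_mutation_rates(cfg)
    sel <- rates$pos >= center - halfwidth & rates$pos <= center + halfwidth
    rates <- rates[sel, ]
    at <- rates$ref %in% c("A", "T")
    sum(rates$p[at]) / sum(rates$p)
  }
  if (target_share == 0) return(0)
  # expected share is monotone increasing in s_at; bracket then solve
  upper <- 1
  while (share_at(upper) < target_share && upper < 1e6) upper <- upper * 10
  uniroot(function(s) share_at(s) - target_share, c(0, upper), tol = 1e-10)$root
}

#' Write ground-truth mutations as TSV
#'
#' Columns `genome`, `pos` (1-based), `ref`, `alt`.
#'
#' @param pool A `genome_pool`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(pool, path) {
  readr::write_tsv(pool$mutations, path)
  invisible(path)
}

#' Write a simulation configuration as key-value text
#'
#' @param config A `simulation_config`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_config_text <- function(config, path) {
  kv <- c(
    reference_id = config$reference$id,
    reference_length = config$reference$length,
    n_guides = nrow(config$guides),
    base_rate = config$base_rate,
    window_halfwidth = config$window_halfwidth,
    window_shape = config$window_shape,
    motif_multiplier_agct = config$motif_multiplier[["agct"]],
    motif_multiplier_wrcy = config$motif_multiplier[["wrcy"]],
    motif_multiplier_other = config$motif_multiplier[["other"]],
    base_multiplier_cg = config$base_multiplier[["cg"]],
    base_multiplier_at = config$base_multiplier[["at"]],
    generations = config$generations,
    n_genomes = config$n_genomes,
    read_length = config$read_length,
    paired = config$paired,
    seq_error_rate = config$seq_error_rate,
    indel_rate = config$indel_rate,
    seed = config$seed
  )
  writeLines(paste(names(kv), unname(kv), sep = "\t"), path)
  invisible(path)
}
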