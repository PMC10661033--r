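# Guide bookkeeping: protospacer/PAM discovery, the distance-based naming
# convention, codon-level annotation of mutations, guide table I/O.
#
# Coordinate frame: `pam3_pos` is the 1-based coding-strand position of the
# 3'-most base of the NGG PAM *on the protospacer strand*. For a coding-strand
# protospacer the PAM reads 5'-NGG-3' left-to-right and pam3_pos is its
# rightmost base; for a template-strand protospacer the PAM occupies a
# coding-strand "CCN" and pam3_pos is the leftmost coding position (the C
# complementary to the template-strand 3' G).

#' Construct a guide design
#'
#' @param spacer 20-nt spacer sequence (identical to the protospacer on its
#'   strand).
#' @param strand `"coding"` or `"template"`: the strand carrying the
#'   protospacer.
#' @param pam3_pos 1-based coding-strand position of the PAM's 3'-most base.
#' @param name Optional guide name (see [name_guide()]).
#' @param reference Optional `reference_amplicon`; when given, the spacer/PAM
#'   consistency invariants are checked against it.
#' @return A one-row tibble with columns `name`, `spacer`, `strand`,
#'   `pam3_pos`.
#' @export
guide_design <- function(spacer, strand = c("coding", "template"), pam3_pos,
                         name = NA_character_, reference = NULL) {
  strand <- match.arg(strand)
  spacer <- toupper(spacer)
  assert_scalar_seq(spacer, "spacer")
  assert_dna_alphabet(spacer, "spacer")
  if (nchar(spacer) != 20L) abort("`spacer` must be 20 nt.")
  g <- tibble(name = name, spacer = spacer, strand = strand,
              pam3_pos = as.integer(pam3_pos))
  if (!is.null(reference)) validate_guides(g, reference)
  g
}

# check spacer/PAM invariants of a guide table against the reference
validate_guides <- function(guides, reference) {
  ref <- as_reference(reference)
  s <- ref$sequence
  for (i in seq_len(nrow(guides))) {
    p <- guides$pam3_pos[i]
    if (guides$strand[i] == "coding") {
      if (p < 23L || p > ref$length) abort("guide PAM not locatable on the reference.")
      pam <- substr(s, p - 2L, p)
      if (substr(pam, 2L, 3L) != "GG") abort(sprintf("no NGG at pam3_pos %d (coding).", p))
      proto <- substr(s, p - 22L, p - 3L)
    } else {
      if (p < 1L || p + 22L > ref$length) abort("guide PAM not locatable on the reference.")
      if (substr(s, p, p + 1L) != "CC") abort(sprintf("no NGG at pam3_pos %d (template).", p))
      proto <- revcomp(substr(s, p + 3L, p + 22L))
    }
    if (proto != guides$spacer[i]) {
      abort(sprintf("spacer of guide %d does not match the protospacer at pam3_pos %d.",
                    i, p))
    }
  }
  invisible(guides)
}

#' Scan a reference for candidate protospacers
#'
#' Returns every 20-nt protospacer followed by an NGG PAM on either strand.
#' Order is deterministic: coding-strand hits 5' to 3', then template-strand
#' hits 5' to 3' on the coding coordinate.
#'
#' @param reference A `reference_amplicon` (or DNA string).
#' @return Tibble of guide designs (`name` is `NA`; assign with
#'   [name_guide()]).
#' @export
#' @examples
#' find_protospacers(paste0(strrep("A", 20), "TGG"))
find_protospacers <- function(reference) {
  ref <- as_reference(reference)
  s <- ref$sequence
  chars <- seq_chars(s)
  n <- ref$length
  hits <- list()
  # coding strand: GG at (p-1, p), protospacer [p-22, p-3]
  gg <- which(chars == "G")
  gg <- gg[gg >= 23L & chars[pmax(gg - 1L, 1L)] == "G"]
  for (p in gg) {
    hits[[length(hits) + 1L]] <- tibble(
      name = NA_character_, spacer = substr(s, p - 22L, p - 3L),
      strand = "coding", pam3_pos = as.integer(p))
  }
  # template strand: CC at (p, p+1) on coding, protospacer revcomp([p+3, p+22])
  cc <- which(chars == "C")
  cc <- cc[cc + 22L <= n & chars[pmin(cc + 1L, n)] == "C"]
  for (p in cc) {
    hits[[length(hits) + 1L]] <- tibble(
      name = NA_character_, spacer = revcomp(substr(s, p + 3L, p + 22L)),
      strand = "template", pam3_pos = as.integer(p))
  }
  if (length(hits) == 0L) {
    return(tibble(name = character(), spacer = character(),
                  strand = character(), pam3_pos = integer()))
  }
  out <- bind_rows(hits)
  arrange(out, factor(.data$strand, levels = c("coding", "template")), .data$pam3_pos)
}

#' Name guides by distance from an anchor
#'
#' Guides are named `<distance><L|R>` with a leading `t` for template-strand
#' protospacers: the distance in bp from the anchor (for example the first
#' base of the codon of interest) to the 3' end of the PAM, `L` when the PAM
#' 3' end lies left of the anchor, `R` when right. A PAM 3' end coinciding
#' with the anchor is reported as distance 0 with side `L`.
#'
#' @param guides Guide tibble (see [guide_design()]).
#' @param anchor 1-based anchor position on the coding strand.
#' @return The guide tibble with `name` filled in.
#' @export
#' @examples
#' g <- guide_design(strrep("A", 20), "coding", pam3_pos = 30)
#' name_guide(g, anchor = 48)$name  # "18L"
name_guide <- function(guides, anchor) {
  anchor <- as.integer(anchor)
  d <- abs(anchor - guides$pam3_pos)
  side <- if_else(guides$pam3_pos < anchor, "L",
                  if_else(guides$pam3_pos > anchor, "R", "L"))
  prefix <- if_else(guides$strand == "template", "t", "")
  mutate(guides, name = paste0(prefix, d, side))
}

#' Reconstruct a PAM position from a guide name
#'
#' Inverse of [name_guide()] given the same anchor.
#'
#' @param name Guide name such as `"t22L"` or `"29R"`.
#' @param anchor 1-based anchor position.
#' @return Tibble with `strand` and `pam3_pos`.
#' @export
parse_guide_name <- function(name, anchor) {
  m <- stringr::str_match(name, "^(t?)(\\d+)([LR])$")
  if (any(is.na(m[, 1]))) abort("guide name must match `t?<distance><L|R>`.")
  d <- as.integer(m[, 3])
  pam3 <- if_else(m[, 4] == "L", anchor - d, anchor + d)
  tibble(name = name,
         strand = if_else(m[, 2] == "t", "template", "coding"),
         pam3_pos = as.integer(pam3))
}

#' Translate a codon change
#'
#' Standard-genetic-code translation of a reference and an alternative codon,
#' flagging silent changes. Vectorised.
#'
#' @param ref_codon,alt_codon DNA triplets.
#' @return Tibble with `aa_ref`, `aa_alt`, `silent`.
#' @export
#' @examples
#' codon_change("TGG", "TTT")  # W -> F
codon_change <- function(ref_codon, alt_codon) {
  ref_codon <- toupper(ref_codon); alt_codon <- toupper(alt_codon)
  ok <- function(x) all(nchar(x) == 3L) && all(grepl("^[ACGT]{3}$", x))
  if (!ok(ref_codon) || !ok(alt_codon)) abort("codons must be A/C/G/T triplets.")
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[ref_codon])
  aa_alt <- unname(code[alt_codon])
  tibble(aa_ref = aa_ref, aa_alt = aa_alt, silent = aa_ref == aa_alt)
}

#' Annotate substitutions with codon effects and feature proximity
#'
#' Maps each substitution onto its codon (given the reference's ORF frame),
#' reports the amino-acid change, and the nearest annotated feature interval
#' with a signed distance: 0 inside the feature, negative when the site lies
#' left of (before) the feature, positive when right of (after) it.
#' Substitutions upstream of the ORF start are annotated as non-coding.
#'
#' @param mutations Tibble with columns `pos`, `ref`, `alt` (1-based).
#' @param reference A `reference_amplicon` with `orf_start` set (and
#'   optionally `features`).
#' @return Tibble with codon index, codons, amino acids, `silent`, `coding`,
#'   `feature`, `feature_distance`.
#' @export
annotate_mutations <- function(mutations, reference) {
  ref <- as_reference(reference)
  if (is.null(ref$orf_start)) abort("reference has no `orf_start`.")
  mutations <- as_tibble(mutations)
  s <- ref$sequence
  rows <- purrr::map(seq_len(nrow(mutations)), function(i) {
    pos <- mutations$pos[i]; alt <- mutations$alt[i]
    if (substr(s, pos, pos) != mutations$ref[i]) {
      abort(sprintf("mutation ref base at %d does not match the reference.", pos))
    }
    coding <- pos >= ref$orf_start && pos <= ref$length
    if (coding) {
      codon_index <- (pos - ref$orf_start) %/% 3L + 1L
      cstart <- ref$orf_start + 3L * (codon_index - 1L)
      coding <- cstart + 2L <= ref$length
    }
    if (!coding) {
      row <- tibble(pos = pos, ref = mutations$ref[i], alt = alt,
                    codon_index = NA_integer_, ref_codon = NA_character_,
                    alt_codon = NA_character_, aa_ref = NA_character_,
                    aa_alt = NA_character_, silent = NA, coding = FALSE)
    } else {
      ref_codon <- substr(s, cstart, cstart + 2L)
      alt_chars <- seq_chars(ref_codon)
      alt_chars[pos - cstart + 1L] <- alt
      alt_codon <- paste(alt_chars, collapse = "")
      cc <- codon_change(ref_codon, alt_codon)
      row <- tibble(pos = pos, ref = mutations$ref[i], alt = alt,
                    codon_index = codon_index, ref_codon = ref_codon,
                    alt_codon = alt_codon, aa_ref = cc$aa_ref,
                    aa_alt = cc$aa_alt, silent = cc$silent, coding = TRUE)
    }
    if (!is.null(ref$features) && nrow(ref$features) > 0L) {
      dist <- dplyr::case_when(
        pos < ref$features$start ~ pos - ref$features$start,
        pos > ref$features$end   ~ pos - ref$features$end,
        TRUE                     ~ 0L
      )
      j <- which.min(abs(dist))
      row$feature <- ref$features$label[j]
      row$feature_distance <- as.integer(dist[j])
    } else {
      row$feature <- NA_character_
      row$feature_distance <- NA_integer_
    }
    row
  })
  bind_rows(rows)
}

#' Read and write guide tables
#'
#' Guides travel as TSV with columns `name`, `spacer`, `strand`, `pam3_pos`
#' (1-based).
#'
#' @param guides Guide tibble.
#' @param path File path.
#' @return `read_guides()` returns a tibble; `write_guides()` returns `path`
#'   invisibly.
#' @export
write_guides <- function(guides, path) {
  readr::write_tsv(guides[, c("name", "spacer", "strand", "pam3_pos")], path)
  invisible(path)
}

#' @rdname write_guides
#' @export
read_guides <- function(path) {
  readr::read_tsv(path, col_types = "ccci", progress = FALSE)
}
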