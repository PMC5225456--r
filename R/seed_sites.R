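#' Seed of a mature miRNA
#'
#' Nucleotides 2-8 (1-based, 5' to 3') of the mature sequence.
#'
#' @param sequence mature miRNA sequence (string, length >= 8) or a
#'   [sequence_record()].
#' @return The 7-nt seed string.
#' @export
seed_of <- function(sequence) {
  if (inherits(sequence, "sequence_record")) sequence <- sequence$sequence
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8) {
    stop_value("mature sequence must be >= 8 nt to define a seed")
  }
  substr(sequence, 2, 8)
}

#' Canonical target-site motifs for a seed
#'
#' Builds the four canonical site motifs as they appear on the target
#' (3'UTR) strand, 5' to 3': `7mer-m8` is the reverse complement of
#' seed positions 2-8, `7mer-A1` the reverse complement of positions
#' 2-7 followed by an `A`, `8mer` the 7mer-m8 followed by an `A`, and
#' `6mer` the reverse complement of positions 2-7. Motifs are emitted
#' in the requested (target) alphabet regardless of whether the miRNA
#' seed was given as RNA or DNA.
#'
#' @param seed 7-nt seed string (from [seed_of()]).
#' @param alphabet target alphabet, `"DNA"` (default) or `"RNA"`.
#' @return Named character vector with elements `8mer`, `7mer-m8`,
#'   `7mer-A1`, `6mer`.
#' @export
site_motifs <- function(seed, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  seed <- toupper(seed)
  if (nchar(seed) != 7) stop_value("seed must be exactly 7 nt")
  # normalise the seed to the target alphabet before complementing
  seed <- if (alphabet == "DNA") chartr("U", "T", seed) else
    chartr("T", "U", seed)
  m8 <- revcomp_seq(seed, alphabet)              # pairs seed 2-8
  six <- revcomp_seq(substr(seed, 1, 6), alphabet)  # pairs seed 2-7
  c("8mer" = paste0(m8, "A"), "7mer-m8" = m8,
    "7mer-A1" = paste0(six, "A"), "6mer" = six)
}

#' Scan a 3'UTR for canonical miRNA seed sites
#'
#' Finds every match of the four canonical motifs on the given UTR
#' (plus strand, 5' to 3') and reports the longest site type per locus:
#' an 8mer subsumes the 7mers it contains, and 7mers subsume the 6mer.
#' Coordinates are 0-based half-open on the supplied sequence.
#'
#' @param utr a [sequence_record()] (DNA) or plain string.
#' @param mirna a [sequence_record()] or mature sequence string
#'   (RNA or DNA).
#' @param report_all if `TRUE`, report all overlapping site types
#'   without subsumption (audit mode).
#' @return A `data.frame` of class `seed_sites` with columns `utr_id`,
#'   `start`, `end` (0-based half-open), `site_type`, `match`.
#' @export
scan_sites <- function(utr, mirna, report_all = FALSE) {
  utr_id <- if (inherits(utr, "sequence_record")) utr$id else "utr"
  useq <- toupper(if (inherits(utr, "sequence_record")) utr$sequence else utr)
  alphabet <- if (grepl("U", useq, fixed = TRUE)) "RNA" else "DNA"
  motifs <- site_motifs(seed_of(mirna), alphabet)
  hits <- do.call(rbind, lapply(names(motifs), function(type) {
    pos <- gregexpr(motifs[[type]], useq, fixed = TRUE)[[1]]
    if (pos[1] == -1) return(NULL)
    data.frame(utr_id = utr_id, start = as.integer(pos) - 1L,
               end = as.integer(pos) - 1L + nchar(motifs[[type]]),
               site_type = type, match = motifs[[type]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) hits <- data.frame(utr_id = character(),
                                        start = integer(), end = integer(),
                                        site_type = character(),
                                        match = character(),
                                        stringsAsFactors = FALSE)
  if (!report_all && nrow(hits) > 1) {
    len <- hits$end - hits$start
    subsumed <- vapply(seq_len(nrow(hits)), function(i) {
      any(len > len[i] & hits$start <= hits$start[i] & hits$end >= hits$end[i])
    }, logical(1))
    hits <- hits[!subsumed, , drop = FALSE]
  }
  hits <- hits[order(hits$start, hits$end - hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("seed_sites", "data.frame")
  hits
}

#' Design a seed-region mutant of a target site
#'
#' Replaces the seed-match heptamer (the bases pairing miRNA positions
#' 2-8) with its complement (not reverse complement), which abolishes
#' canonical pairing while preserving length and base composition
#' class. The mutant is re-scanned; if the substitution accidentally
#' created a new canonical site, the reverse complement is tried as the
#' documented fallback, and an error is raised if that also fails.
#'
#' @param utr a [sequence_record()] (DNA).
#' @param site one row of a [scan_sites()] result (the site to
#'   mutate); pass the scan result itself to mutate its first site.
#' @param mirna the miRNA used for the rescan guard.
#' @return A [sequence_record()] for the mutant (id suffixed `_mut`),
#'   with attribute `mutation` describing the substitution.
#' @export
mutate_seed_site <- function(utr, site, mirna) {
  stopifnot(inherits(utr, "sequence_record"))
  if (is.data.frame(site)) {
    if (nrow(site) == 0) stop_value("no site to mutate (empty site list)")
    site <- site[1, , drop = FALSE]
  }
  start <- site$start
  end <- site$end
  if (start < 0 || end > nchar(utr$sequence)) {
    stop_value("site interval outside the UTR")
  }
  # mutate the 7 bases pairing seed positions 2-8: for 7mer-A1 and 8mer
  # the terminal A opposite position 1 is left intact
  m8_end <- if (site$site_type %in% c("8mer", "7mer-A1")) end - 1L else end
  m8_start <- m8_end - 7L
  if (m8_start < 0) m8_start <- 0L
  region <- substr(utr$sequence, m8_start + 1, m8_end)
  for (replacement in c(complement_seq(region, utr$alphabet),
                        revcomp_seq(region, utr$alphabet))) {
    mutant_seq <- paste0(substr(utr$sequence, 1, m8_start), replacement,
                         substr(utr$sequence, m8_end + 1,
                                nchar(utr$sequence)))
    mutant <- sequence_record(paste0(utr$id, "_mut"), mutant_seq,
                              utr$alphabet)
    if (nrow(scan_sites(mutant, mirna)) == 0) {
      attr(mutant, "mutation") <- sprintf("[%d,%d) %s>%s", m8_start, m8_end,
                                          region, replacement)
      return(mutant)
    }
  }
  stop_value("mutation created a new canonical site and the fallback ",
             "substitution did too")
}
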