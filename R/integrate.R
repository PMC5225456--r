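#' miRNA-to-family map from a target table
#'
#' @param targets a [target_table()].
#' @return Named character vector: names are miRNA ids, values family
#'   ids.
#' @export
family_map <- function(targets) {
  fams <- rep(names(targets$mirnas), lengths(targets$mirnas))
  setNames(fams, unlist(targets$mirnas, use.names = FALSE))
}

#' Intersect significant families with differentially expressed miRNAs
#'
#' Candidates are the DE miRNAs whose family is flagged significant in
#' the enrichment screen, annotated with the family statistics and the
#' miRNA's fold change, and ranked by family q ascending, NPES
#' descending, then miRNA id. DE miRNAs that map to no tested family
#' are excluded (and counted in attribute `n_unmapped`), mirroring the
#' upstream conservation filter.
#'
#' @param enrichment an `enrichment_results` data frame from
#'   [screen_families()].
#' @param de_records a [fold_changes()] result (supplies the DE set and
#'   fold-change annotation).
#' @param fmap a [family_map()].
#' @return A `data.frame` of class `candidate_records` with columns
#'   `rank`, `mirna_id`, `family_id`, `npes`, `q_value`, `fold_change`,
#'   `direction`; attributes `n_unmapped` and `n_families`.
#' @export
intersect_candidates <- function(enrichment, de_records, fmap) {
  de_ids <- de_mirna_set(de_records)
  mapped <- de_ids[de_ids %in% names(fmap)]
  n_unmapped <- length(de_ids) - length(mapped)
  if (n_unmapped > 0) {
    message(n_unmapped, " DE miRNA(s) map to no tested family; excluded")
  }
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  keep <- mapped[fmap[mapped] %in% sig$family_id]
  fam <- unname(fmap[keep])
  idx <- match(fam, enrichment$family_id)
  fcidx <- match(keep, de_records$mirna_id)
  df <- data.frame(mirna_id = keep, family_id = fam,
                   npes = enrichment$npes[idx],
                   q_value = enrichment$q_value[idx],
                   fold_change = de_records$fold_change[fcidx],
                   direction = de_records$direction[fcidx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$q_value, -df$npes, df$mirna_id, method = "radix"), ,
           drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  attr(df, "n_unmapped") <- n_unmapped
  attr(df, "n_families") <- length(unique(df$family_id))
  class(df) <- c("candidate_records", "data.frame")
  df
}

#' Stage-count summary of a screen run
#'
#' @param enrichment an `enrichment_results` data frame.
#' @param de_records a [fold_changes()] result.
#' @param candidates an [intersect_candidates()] result.
#' @return A named list of counts: families tested, significant
#'   families, DE miRNAs, candidate miRNAs, candidate families.
#' @export
screen_summary <- function(enrichment, de_records, candidates) {
  list(families_tested = nrow(enrichment),
       significant_families = sum(enrichment$significant),
       de_mirnas = sum(de_records$passes),
       candidate_mirnas = nrow(candidates),
       candidate_families = attr(candidates, "n_families") %||%
         length(unique(candidates$family_id)))
}

#' Write the candidate table and run summary
#'
#' Writes the candidate table as tab-separated values and a structured
#' plain-text run summary next to it (same path with suffix
#' `.summary.txt`).
#'
#' @param candidates an [intersect_candidates()] result.
#' @param summary a [screen_summary()] list.
#' @param out_path path of the candidate TSV.
#' @return `summary`, invisibly.
#' @export
write_report <- function(candidates, summary, out_path) {
  utils::write.table(as.data.frame(candidates), out_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lines <- c("screen run summary",
             sprintf("families_tested\t%d", summary$families_tested),
             sprintf("significant_families\t%d", summary$significant_families),
             sprintf("de_mirnas\t%d", summary$de_mirnas),
             sprintf("candidate_mirnas\t%d", summary$candidate_mirnas),
             sprintf("candidate_families\t%d", summary$candidate_families))
  writeLines(lines, paste0(out_path, ".summary.txt"))
  invisible(summary)
}

#' Run the full miRNA prioritisation screen
#'
#' Chains propagation, NPES enrichment, median normalisation,
#' fold-change filtering and candidate intersection over a set of
#' inputs as produced by [generate_screen_inputs()] (or loaded from
#' files with the `read_*` functions).
#'
#' @param inputs list with elements `network`, `scores`, `targets`,
#'   `expr`, and optionally `family_map` (derived from `targets` when
#'   absent).
#' @param params a [propagation_params()].
#' @param n_permutations permutations per family (default 1000).
#' @param fdr_threshold BH q threshold (default 0.05).
#' @param up_threshold,down_threshold fold-change bounds (defaults
#'   1.25 / 0.75).
#' @param rng_seed integer seed for the permutation streams.
#' @return A list with `enrichment`, `de`, `candidates`, `summary`.
#' @export
run_screen <- function(inputs, params = propagation_params(),
                       n_permutations = 1000, fdr_threshold = 0.05,
                       up_threshold = 1.25, down_threshold = 0.75,
                       rng_seed = 1L) {
  prop <- propagate_all(inputs$targets, inputs$network, params)
  enrichment <- screen_families(prop, inputs$scores,
                                n_permutations = n_permutations,
                                fdr_threshold = fdr_threshold,
                                rng_seed = rng_seed)
  de <- fold_changes(median_normalize(inputs$expr),
                     up_threshold = up_threshold,
                     down_threshold = down_threshold)
  fmap <- inputs$family_map %||% family_map(inputs$targets)
  candidates <- intersect_candidates(enrichment, de, fmap)
  list(enrichment = enrichment, de = de, candidates = candidates,
       summary = screen_summary(enrichment, de, candidates))
}
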