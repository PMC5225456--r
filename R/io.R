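#' Construct a miRNA-family target table
#'
#' A target table records, per conserved miRNA family, its member miRNA
#' identifiers, a family conservation score and the set of predicted
#' target genes. It is the first-stage input of the network-propagation
#' screen: each family's target set becomes the seed of a propagation run.
#'
#' @param family_id character vector of unique family identifiers.
#' @param mirna_ids list of character vectors, member miRNAs per family.
#' @param conservation_score finite numeric vector, one per family.
#' @param target_gene_ids list of character vectors, non-empty target
#'   gene sets per family.
#' @return An object of class `target_table`.
#' @export
target_table <- function(family_id, mirna_ids, conservation_score, target_gene_ids) {
  family_id <- as.character(family_id)
  if (anyDuplicated(family_id)) {
    stop_value("duplicate family_id: ",
               paste(unique(family_id[duplicated(family_id)]), collapse = ", "))
  }
  conservation_score <- as.numeric(conservation_score)
  if (any(!is.finite(conservation_score))) {
    stop_value("non-finite conservation_score")
  }
  stopifnot(length(mirna_ids) == length(family_id),
            length(conservation_score) == length(family_id),
            length(target_gene_ids) == length(family_id))
  target_gene_ids <- lapply(target_gene_ids, function(g) unique(as.character(g)))
  if (any(lengths(target_gene_ids) == 0) && length(family_id) > 0) {
    stop_value("empty target set for family: ",
               family_id[which(lengths(target_gene_ids) == 0)[1]])
  }
  structure(
    list(families = data.frame(family_id = family_id,
                               conservation_score = conservation_score,
                               stringsAsFactors = FALSE),
         mirnas = setNames(lapply(mirna_ids, as.character), family_id),
         targets = setNames(target_gene_ids, family_id)),
    class = "target_table")
}

#' @exportS3Method base::print
print.target_table <- function(x, ...) {
  cat(sprintf("target_table: %d families, %d miRNAs, %d distinct target genes\n",
              nrow(x$families), sum(lengths(x$mirnas)),
              length(unique(unlist(x$targets)))))
  invisible(x)
}

#' Read a miRNA-family target table
#'
#' Reads a tab-separated file with header columns `family_id`,
#' `mirna_ids` (comma-joined member miRNAs), `conservation_score` and
#' `gene_id`, one row per family-gene pair, and groups rows into one
#' record per family. Families below the conservation threshold are
#' excluded, mirroring the screen's restriction to highly conserved
#' families.
#'
#' @param path path to the tab-separated file.
#' @param min_conservation minimum family conservation score retained
#'   (default 2).
#' @return A [target_table()].
#' @export
read_target_table <- function(path, min_conservation = 2) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  required <- c("family_id", "mirna_ids", "conservation_score", "gene_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_format("target table is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(target_table(character(), list(), numeric(), list()))
  }
  cons <- suppressWarnings(as.numeric(df$conservation_score))
  if (any(is.na(cons))) {
    bad <- which(is.na(cons))[1]
    stop_format("non-numeric conservation_score at line ", bad + 1L,
                ": '", df$conservation_score[bad], "'")
  }
  keep <- split(seq_len(nrow(df)), df$family_id)
  fam_ids <- names(keep)
  fam_cons <- vapply(keep, function(i) cons[i][1], numeric(1))
  fam_mirnas <- lapply(keep, function(i) {
    unique(trimws(strsplit(df$mirna_ids[i][1], ",", fixed = TRUE)[[1]]))
  })
  fam_targets <- lapply(keep, function(i) unique(df$gene_id[i]))
  retained <- fam_cons >= min_conservation
  target_table(fam_ids[retained], fam_mirnas[retained],
               fam_cons[retained], fam_targets[retained])
}

#' Write a target table in the package's tab-separated dialect
#'
#' @param x a [target_table()].
#' @param path output path.
#' @export
write_target_table <- function(x, path) {
  rows <- do.call(rbind, c(list(
    data.frame(family_id = character(), mirna_ids = character(),
               conservation_score = numeric(), gene_id = character())),
    lapply(seq_len(nrow(x$families)), function(i) {
      fid <- x$families$family_id[i]
      data.frame(family_id = fid,
                 mirna_ids = paste(x$mirnas[[fid]], collapse = ","),
                 conservation_score = x$families$conservation_score[i],
                 gene_id = x$targets[[fid]],
                 stringsAsFactors = FALSE)
    })))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed regulatory edge list
#'
#' Two tab-separated columns (`source`, `target`) with a header row;
#' lines starting with `#` are comments. Edges are deduplicated and
#' self-loops dropped (their count is kept in attribute `n_self_loops`
#' and reported via a message).
#'
#' @param path path to the edge-list file.
#' @return A `data.frame` of class `edge_list` with columns `source`,
#'   `target`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(edge_list(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    stop_format("edge list line ", lineno[bad], " has ", nf[bad],
                " field(s); expected 2")
  }
  src <- vapply(fields, `[[`, character(1), 1)[-1]
  tgt <- vapply(fields, `[[`, character(1), 2)[-1]
  edge_list(src, tgt)
}

#' Construct a directed edge list (deduplicated, self-loops dropped)
#'
#' @param source,target character vectors of equal length.
#' @return A `data.frame` of class `edge_list`; attribute `n_self_loops`
#'   holds the number of dropped self-loops.
#' @export
edge_list <- function(source, target) {
  source <- as.character(source)
  target <- as.character(target)
  stopifnot(length(source) == length(target))
  loop <- source == target
  n_loops <- sum(loop)
  if (n_loops > 0) {
    message("dropping ", n_loops, " self-loop(s)")
  }
  df <- unique(data.frame(source = source[!loop], target = target[!loop],
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(df, n_self_loops = n_loops, class = c("edge_list", "data.frame"))
}

#' Write an edge list in the package's tab-separated dialect
#'
#' @param x an [edge_list()].
#' @param path output path.
#' @export
write_edge_list <- function(x, path) {
  utils::write.table(data.frame(source = x$source, target = x$target),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read addiction-gene reliability scores
#'
#' Two tab-separated columns (`gene_id`, `reliability`) with header.
#' Reliability must be strictly positive; duplicate genes are collapsed
#' to their maximum reliability (evidence scores: the strongest record
#' wins). The log-transformed reliability used as the enrichment weight
#' is computed on load.
#'
#' @param path path to the score file.
#' @param log_base base of the log transform (default natural log).
#' @return A `data.frame` of class `gene_scores` with columns `gene_id`,
#'   `reliability`, `log_reliability`.
#' @export
read_gene_scores <- function(path, log_base = exp(1)) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene_id", "reliability")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_format("gene score file is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  gene_scores(df$gene_id, as.numeric(df$reliability), log_base = log_base)
}

#' Construct a gene reliability score list
#'
#' @param gene_id character vector.
#' @param reliability positive numeric vector.
#' @param log_base base of the log transform (default natural log).
#' @return A `data.frame` of class `gene_scores`.
#' @export
gene_scores <- function(gene_id, reliability, log_base = exp(1)) {
  gene_id <- as.character(gene_id)
  reliability <- as.numeric(reliability)
  stopifnot(length(gene_id) == length(reliability))
  bad <- !is.finite(reliability) | reliability <= 0
  if (any(bad)) {
    stop_value("non-positive reliability for gene: ", gene_id[which(bad)[1]])
  }
  if (anyDuplicated(gene_id)) {
    n_dup <- sum(duplicated(gene_id))
    message("collapsing ", n_dup, " duplicate gene record(s) by max reliability")
    reliability <- vapply(split(reliability, gene_id), max, numeric(1))
    gene_id <- names(reliability)
  }
  df <- data.frame(gene_id = gene_id, reliability = unname(reliability),
                   log_reliability = log(unname(reliability), base = log_base),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("gene_scores", "data.frame"))
}

#' Write gene reliability scores (raw reliabilities only)
#'
#' @param x a [gene_scores()] data frame.
#' @param path output path.
#' @export
write_gene_scores <- function(x, path) {
  utils::write.table(data.frame(gene_id = x$gene_id, reliability = x$reliability),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a two-group miRNA expression matrix
#'
#' @param signals numeric matrix (miRNAs x samples) of non-negative
#'   signals, with row and column names.
#' @param groups named character vector mapping every sample (column)
#'   to `"CS"` (chronic saline / control) or `"CH"` (chronic heroin /
#'   treated).
#' @param normalized logical; whether per-array median normalisation has
#'   been applied.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(signals, groups, normalized = FALSE) {
  stopifnot(is.matrix(signals), !is.null(rownames(signals)),
            !is.null(colnames(signals)))
  if (any(!is.finite(signals)) || any(signals < 0)) {
    stop_value("expression signals must be finite and non-negative")
  }
  missing <- setdiff(colnames(signals), names(groups))
  if (length(missing)) {
    stop_value("sample(s) missing from group map: ",
               paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(signals)]
  if (!all(groups %in% c("CS", "CH"))) {
    stop_value("groups must be 'CS' or 'CH'")
  }
  if (length(unique(groups)) < 2) {
    stop_value("both groups (CS and CH) must be non-empty")
  }
  structure(list(signals = signals, groups = groups,
                 normalized = isTRUE(normalized)),
            class = "expr_matrix")
}

#' @exportS3Method base::print
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d miRNAs x %d samples (CS: %d, CH: %d), %s\n",
              nrow(x$signals), ncol(x$signals), sum(x$groups == "CS"),
              sum(x$groups == "CH"),
              if (x$normalized) "median-normalized" else "raw"))
  invisible(x)
}

#' Read a miRNA expression matrix and its sample group map
#'
#' The matrix file is tab-separated with header: first column `mirna_id`,
#' remaining columns per-sample signals. The groups file has header
#' columns `sample_id`, `group` with group values `CS`/`CH`.
#'
#' @param path matrix file path.
#' @param groups_path group map file path.
#' @return An `expr_matrix` with `normalized = FALSE`.
#' @export
read_expression_matrix <- function(path, groups_path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop_format("expression matrix needs >= 2 columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  gdf <- utils::read.delim(groups_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("sample_id", "group"), names(gdf))
  if (length(missing)) {
    stop_format("group file is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  expr_matrix(m, setNames(as.character(gdf$group), gdf$sample_id),
              normalized = FALSE)
}

#' Write an expression matrix (and optionally its group map)
#'
#' @param x an [expr_matrix()].
#' @param path matrix output path.
#' @param groups_path optional group-map output path.
#' @export
write_expression_matrix <- function(x, path, groups_path = NULL) {
  df <- data.frame(mirna_id = rownames(x$signals), x$signals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(data.frame(sample_id = names(x$groups),
                                  group = unname(x$groups)),
                       groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a validated sequence record
#'
#' @param id record identifier.
#' @param sequence nucleotide string (case-insensitive input; stored
#'   uppercase).
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(id, sequence, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop_value("empty sequence for record '", id, "'")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ok <- chars %in% alphabet_letters(alphabet)
  if (!all(ok)) {
    pos <- which(!ok)[1]
    stop_value("illegal ", alphabet, " character '", chars[pos],
               "' in record '", id, "' at position ", pos)
  }
  structure(list(id = as.character(id), sequence = sequence,
                 alphabet = alphabet),
            class = "sequence_record")
}

#' Read a FASTA file into validated sequence records
#'
#' Sequences are uppercased and validated against the declared alphabet
#' (`U` and `T` are not interconverted here; use the alphabet that
#' matches the file).
#'
#' @param path FASTA file path.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return A list of [sequence_record()]s.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1)
  mapply(function(id, s) sequence_record(id, s, alphabet),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records a list of [sequence_record()]s.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(
    setNames(vapply(records, `[[`, character(1), "sequence"),
             vapply(records, `[[`, character(1), "id")))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
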