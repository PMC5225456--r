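#' Propagation parameters (random walk with restart)
#'
#' @param restart_alpha restart probability in `(0, 1]` (default 0.5);
#'   the fraction of mass returned to the seed distribution at each
#'   step. `alpha = 1` reproduces the seed vector exactly.
#' @param tolerance L1 convergence tolerance (default 1e-8).
#' @param max_iterations iteration cap (default 1000).
#' @param direction `"downstream"` (follow regulation, TF to regulon;
#'   default) or `"upstream"` (against regulation).
#' @return An object of class `propagation_params`.
#' @export
propagation_params <- function(restart_alpha = 0.5, tolerance = 1e-8,
                               max_iterations = 1000,
                               direction = c("downstream", "upstream")) {
  direction <- match.arg(direction)
  if (!(restart_alpha > 0 && restart_alpha <= 1)) {
    stop_value("restart_alpha must be in (0, 1]")
  }
  if (tolerance <= 0) stop_value("tolerance must be > 0")
  if (max_iterations < 1) stop_value("max_iterations must be >= 1")
  structure(list(restart_alpha = restart_alpha, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 direction = direction),
            class = "propagation_params")
}

#' Build the network transition operator
#'
#' Returns a sparse matrix `W` over `gene_universe` with
#' `W[source, target] = 1 / in-degree(target)`: each gene's incoming
#' weights sum to 1 when it has any parent and to 0 otherwise
#' (column-stochastic where defined). Mass is propagated along edge
#' direction by applying `t(W)`; genes with no parents receive no
#' propagated mass.
#'
#' @param edges an [edge_list()].
#' @param gene_universe character vector containing every edge endpoint
#'   (isolated genes permitted).
#' @return A sparse `dgCMatrix` with dimnames `gene_universe`.
#' @export
build_transition_operator <- function(edges, gene_universe) {
  gene_universe <- as.character(gene_universe)
  endpoints <- unique(c(edges$source, edges$target))
  outside <- setdiff(endpoints, gene_universe)
  if (length(outside)) {
    stop_value("edge endpoint(s) outside gene universe: ",
               paste(utils::head(outside, 3), collapse = ", "))
  }
  n <- length(gene_universe)
  i <- match(edges$source, gene_universe)
  j <- match(edges$target, gene_universe)
  indeg <- tabulate(j, nbins = n)
  Matrix::sparseMatrix(i = i, j = j, x = 1 / indeg[j], dims = c(n, n),
                       dimnames = list(gene_universe, gene_universe))
}

#' Seed distribution of a miRNA family
#'
#' Uniform mass over the family's targets that are present in the gene
#' universe. Families with no in-universe target cannot be propagated
#' and yield `NULL` (a skip signal the caller logs).
#'
#' @param targets character vector of the family's target gene ids.
#' @param gene_universe character vector of network genes.
#' @return A named numeric vector summing to 1, or `NULL` if no target
#'   is in the universe.
#' @export
seed_vector <- function(targets, gene_universe) {
  present <- intersect(unique(targets), gene_universe)
  if (length(present) == 0) return(NULL)
  p0 <- setNames(numeric(length(gene_universe)), gene_universe)
  p0[present] <- 1 / length(present)
  p0
}

#' Propagate a seed distribution by random walk with restart
#'
#' Iterates `p <- (1 - alpha) * t(W) %*% p + alpha * p0` until the L1
#' change falls below `tolerance`. The stationary point equals the
#' closed form `alpha * solve(I - (1 - alpha) * t(W)) %*% p0` (see
#' [propagate_exact()], the dense oracle used for verification).
#'
#' @param W transition operator from [build_transition_operator()].
#' @param p0 seed distribution over the same universe, summing to 1.
#' @param params a [propagation_params()].
#' @param family_id optional identifier carried into the result.
#' @return An object of class `propagation_result` with elements
#'   `family_id`, `effect` (named non-negative vector), `seed_genes`,
#'   `iterations_used`, `converged`.
#' @export
propagate <- function(W, p0, params = propagation_params(),
                      family_id = NA_character_) {
  stopifnot(length(p0) == nrow(W))
  if (abs(sum(p0) - 1) > 1e-6) stop_value("seed vector must sum to 1")
  alpha <- params$restart_alpha
  op <- if (params$direction == "downstream") Matrix::t(W) else W
  p <- p0
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    p_new <- (1 - alpha) * as.numeric(op %*% p) + alpha * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < params$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("propagation did not converge in ", params$max_iterations,
            " iterations (family ", family_id, ")")
  }
  names(p) <- rownames(W)
  structure(list(family_id = family_id, effect = p,
                 seed_genes = names(p0)[p0 > 0],
                 iterations_used = iter, converged = converged),
            class = "propagation_result")
}

#' Closed-form propagation (dense linear solve)
#'
#' Computes `alpha * solve(I - (1 - alpha) * op) %*% p0` with `op` the
#' applied operator (`t(W)` downstream). This is the independent
#' reference solution for [propagate()]; use it on small networks only.
#'
#' @inheritParams propagate
#' @return A named numeric effect vector.
#' @export
propagate_exact <- function(W, p0, params = propagation_params()) {
  alpha <- params$restart_alpha
  op <- as.matrix(if (params$direction == "downstream") Matrix::t(W) else W)
  eff <- alpha * solve(diag(nrow(op)) - (1 - alpha) * op, p0)
  setNames(as.numeric(eff), rownames(W))
}

#' Propagate every family of a target table
#'
#' Builds the transition operator once and runs [propagate()] per
#' family. Families with no in-universe target are skipped; their ids
#' are attached as attribute `skipped_families` and reported via a
#' message.
#'
#' @param targets a [target_table()].
#' @param edges an [edge_list()].
#' @param params a [propagation_params()].
#' @param gene_universe gene universe; defaults to the union of edge
#'   endpoints and all family targets.
#' @return A list of `propagation_result` in table order, with
#'   attribute `skipped_families`.
#' @export
propagate_all <- function(targets, edges, params = propagation_params(),
                          gene_universe = NULL) {
  if (is.null(gene_universe)) {
    gene_universe <- sort(unique(c(edges$source, edges$target,
                                   unlist(targets$targets, use.names = FALSE))))
  }
  W <- build_transition_operator(edges, gene_universe)
  skipped <- character(0)
  results <- list()
  for (fid in targets$families$family_id) {
    p0 <- seed_vector(targets$targets[[fid]], gene_universe)
    if (is.null(p0)) {
      skipped <- c(skipped, fid)
      next
    }
    results[[length(results) + 1L]] <- propagate(W, p0, params,
                                                 family_id = fid)
  }
  if (length(skipped)) {
    message("skipped ", length(skipped),
            " family(ies) with no in-universe target: ",
            paste(skipped, collapse = ", "))
  }
  attr(results, "skipped_families") <- skipped
  results
}
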