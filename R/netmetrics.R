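# Weighted directed graph node metrics extracted from connectivity matrices,
# and assembly of the contacts x (6 metrics x 13 measures) feature table.
#
# Convention: connectivity matrices have destination rows and source columns,
# so the walk/path adjacency (edge s -> d) is the transpose. Strengths are
# computed on the raw matrix; the walk and path metrics (first passage,
# clustering, eccentricity, betweenness) operate on the matrix scaled to
# [0, 1] by its maximum, because the 13 measures live on incommensurable
# scales.

#' In- and out-strength of every node
#'
#' `in_strength[d]` is the sum of inward link weights (row sums),
#' `out_strength[s]` the sum of outward link weights (column sums).
#'
#' @param C connectivity matrix (rows = destination, columns = source).
#' @return list with `in_strength` and `out_strength` vectors.
#' @export
node_strengths <- function(C) {
  list(in_strength = rowSums(C), out_strength = colSums(C))
}

#' Scale a matrix to \[0, 1\] by its maximum
#' @noRd
scale01 <- function(C) {
  m <- max(C)
  if (m > 0) C / m else C
}

#' Inbound mean first passage time of every node
#'
#' Random-walk transition probabilities are the row-normalised walk adjacency
#' (rows with zero out-strength replaced by a uniform step to the other
#' nodes). For each target node the expected hitting times from all other
#' nodes solve the absorbing-chain linear system `(I - Q) t = 1`; the node
#' value is the mean hitting time over all starting nodes. Singular systems
#' (absorbing structure) fall back to the finite cap `10 * N^2` with a
#' warning.
#'
#' @param C connectivity matrix (destination rows); scaled internally.
#' @return numeric vector of inbound mean first passage times.
#' @export
mean_first_passage <- function(C) {
  W <- t(scale01(C))                       # W[s, d] = weight of edge s -> d
  N <- nrow(W)
  rs <- rowSums(W)
  P <- W / ifelse(rs > 0, rs, 1)
  for (i in which(rs == 0)) {
    P[i, ] <- 1 / (N - 1); P[i, i] <- 0
  }
  vapply(seq_len(N), function(k) {
    Q <- P[-k, -k, drop = FALSE]
    t_k <- tryCatch(solve(diag(N - 1) - Q, rep(1, N - 1)),
                    error = function(e) {
                      warning("mfpt: singular system for node ", k,
                              "; capped at 10*N^2")
                      rep(10 * N^2, N - 1)
                    })
    mean(t_k)
  }, numeric(1))
}

#' Fagiolo weighted-directed clustering coefficient
#'
#' With the scaled walk adjacency W and its elementwise cube root
#' \eqn{\hat W}, the triangle intensity is
#' \eqn{t_i = \tfrac12 [(\hat W + \hat W^T)^3]_{ii}} and
#' \eqn{C_i = t_i / [d^{tot}_i (d^{tot}_i - 1) - 2 d^{\leftrightarrow}_i]},
#' with total and bilateral degrees from the binarised matrix; 0 when the
#' denominator is non-positive.
#'
#' @param C connectivity matrix (destination rows); scaled internally.
#' @return numeric vector of clustering coefficients.
#' @export
clustering_wd <- function(C) {
  W <- t(scale01(C))
  diag(W) <- 0
  Wh <- W^(1 / 3)
  Sym <- Wh + t(Wh)
  t_i <- diag(Sym %*% Sym %*% Sym) / 2
  A <- (W > 0) + 0
  d_tot <- rowSums(A) + colSums(A)
  d_bi <- diag(A %*% A)
  denom <- d_tot * (d_tot - 1) - 2 * d_bi
  ifelse(denom > 0, t_i / denom, 0)
}

#' Shortest-path length matrix of the connectivity graph
#'
#' Edge lengths are `1/weight` for positive weights (absent otherwise);
#' distances follow edge direction (source to destination).
#' @noRd
path_lengths <- function(C) {
  W <- t(scale01(C))
  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  igraph::distances(g, mode = "out", algorithm = "dijkstra")
}

#' Outbound node eccentricity
#'
#' Maximal finite shortest-path length from a node to any other node; nodes
#' reaching no one are imputed with the maximal finite eccentricity in the
#' graph so the feature table stays finite.
#'
#' @param C connectivity matrix (destination rows); scaled internally.
#' @return numeric vector of eccentricities.
#' @export
node_eccentricity <- function(C) {
  D <- path_lengths(C)
  diag(D) <- NA
  ecc <- apply(D, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) max(f) else NA_real_
  })
  if (anyNA(ecc)) {
    mx <- if (all(is.na(ecc))) 0 else max(ecc, na.rm = TRUE)
    ecc[is.na(ecc)] <- mx
  }
  ecc
}

#' Normalised betweenness centrality
#'
#' Brandes betweenness on the `1/weight` length graph, divided by
#' `(N - 1)(N - 2)`.
#'
#' @param C connectivity matrix (destination rows); scaled internally.
#' @return numeric vector of betweenness values in \[0, 1\].
#' @export
node_betweenness <- function(C) {
  N <- nrow(C)
  if (N < 3) stop("graph-too-small: betweenness needs N >= 3")
  W <- t(scale01(C))
  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  igraph::betweenness(g, directed = TRUE) / ((N - 1) * (N - 2))
}

#' All six node metrics of one connectivity matrix
#'
#' @param C connectivity matrix (destination rows, source columns).
#' @return data frame with columns `in_strength`, `out_strength`,
#'   `first_passage`, `clustering`, `eccentricity`, `betweenness` (one row
#'   per node).
#' @export
node_metrics <- function(C) {
  s <- node_strengths(C)
  data.frame(in_strength = s$in_strength,
             out_strength = s$out_strength,
             first_passage = mean_first_passage(C),
             clustering = clustering_wd(C),
             eccentricity = node_eccentricity(C),
             betweenness = node_betweenness(C))
}

#' Assemble the per-contact feature table from connectivity stacks
#'
#' Node metrics are computed per (measure, epoch, subsample run) and averaged
#' across epochs and runs for each contact; contacts absent from a run
#' contribute only to the runs containing them. Columns are ordered
#' measure-major (`<measure>__<metric>`), giving 6 x 13 = 78 features for the
#' full measure set.
#'
#' @param stacks list of `conn_stack` objects (one per epoch x run).
#' @param channel_sets list of integer channel-index vectors, parallel to
#'   `stacks`, mapping each stack's rows to contact indices.
#' @param soz_mask logical SOZ flag per contact (full channel indexing).
#' @param patient_id identifier stored in the table.
#' @param per_epoch if TRUE, no averaging: one table row per
#'   (contact, stack), with a `stack` provenance column.
#' @return data frame of class `feature_table`: `patient`, `contact`, `soz`,
#'   then the feature columns.
#' @export
build_feature_table <- function(stacks, channel_sets, soz_mask,
                                patient_id = "pt", per_epoch = FALSE) {
  stopifnot(length(stacks) >= 1, length(stacks) == length(channel_sets))
  measures <- names(stacks[[1]])
  feat_names <- as.vector(t(outer(measures, METRICS, paste, sep = "__")))

  per_stack <- lapply(seq_along(stacks), function(si) {
    st <- stacks[[si]]
    vals <- do.call(cbind, lapply(measures, function(m)
      as.matrix(node_metrics(st[[m]]))))
    colnames(vals) <- feat_names
    data.frame(contact = channel_sets[[si]], stack = si, vals,
               check.names = FALSE)
  })
  all_rows <- do.call(rbind, per_stack)

  if (per_epoch) {
    tab <- all_rows
  } else {
    agg <- stats::aggregate(all_rows[feat_names],
                            by = list(contact = all_rows$contact), mean)
    tab <- agg
  }
  dropped <- setdiff(which(soz_mask | !soz_mask), unique(all_rows$contact))
  if (length(dropped) && !per_epoch)
    warning("contacts in no subsample run dropped: ",
            paste(dropped, collapse = ", "))
  out <- data.frame(patient = patient_id, contact = tab$contact,
                    soz = soz_mask[tab$contact],
                    tab[setdiff(names(tab), "contact")],
                    check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature column names of a feature table
#' @noRd
feature_cols <- function(tab)
  setdiff(names(tab), c("patient", "contact", "soz", "stack", "period"))
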