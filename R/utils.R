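# Internal helpers shared across modules.

#' @importFrom stats .lm.fit
NULL

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a base seed and context labels
#'
#' Cheap integer hash; keeps every stage / patient / run on its own stream
#' while staying inside 32-bit integer range.
#' @noRd
sub_seed <- function(seed, ...) {
  parts <- c(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    codes <- utf8ToInt(paste0(as.character(p), "|"))
    for (ch in codes) h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483647) + 1L
}

#' Companion-matrix spectral radius of a VAR coefficient set
#' @param A list of p square lag matrices
#' @noRd
companion_radius <- function(A) {
  p <- length(A)
  n <- nrow(A[[1]])
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[1:n, ((k - 1) * n + 1):(k * n)] <- A[[k]]
  if (p > 1) comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Canonical measure and metric identifiers
#' @noRd
MEASURES <- c("ANM", "IGCI", "CDS", "RECI", "CCE", "DI",
              "GD", "PSI", "DTF", "DCOH", "PDC", "SGC", "LMFIT")

#' @noRd
MEASURE_CATEGORIES <- c(ANM = "info", IGCI = "info", CDS = "info", RECI = "info",
                        CCE = "info", DI = "info",
                        GD = "freq", PSI = "freq", DTF = "freq", DCOH = "freq",
                        PDC = "freq", SGC = "freq",
                        LMFIT = "time")

#' @noRd
METRICS <- c("in_strength", "out_strength", "first_passage", "clustering",
             "eccentricity", "betweenness")

#' Area under the ROC curve by the rank-sum formula
#'
#' Threshold-free AUC for binary labels; ties in scores handled by midranks.
#' @param scores numeric classifier scores (higher = more positive)
#' @param labels logical or 0/1 vector, TRUE/1 = positive class
#' @return AUC in \[0, 1\]
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("auc_score: both classes required")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensure a matrix is a clean non-negative zero-diagonal connectivity matrix
#' @noRd
as_conn_matrix <- function(m, measure, epoch = NA_character_) {
  diag(m) <- 0
  m[!is.finite(m)] <- 0
  m[m < 0] <- 0
  structure(m, measure = measure, epoch = epoch)
}
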