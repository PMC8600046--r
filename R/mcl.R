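#' Markov clustering (MCL) of an interaction network
#'
#' Detects network modules by Markov clustering: random-walk flow on the
#' graph is alternately expanded (matrix power) and inflated (elementwise
#' power followed by column re-normalisation) until the flow matrix is
#' idempotent; the attractor structure of the limit matrix defines the
#' modules. Self-loops are added before iteration, the standard device to
#' avoid period-two oscillation on bipartite-ish structures.
#'
#' @param net An `interactome` or igraph graph.
#' @param inflation Inflation exponent (> 1); larger values give finer
#'   modules. Default 2.
#' @param expansion Expansion power (integer >= 2). Default 2.
#' @param pruning Entries below this value are zeroed after each
#'   inflation, keeping the flow matrix sparse.
#' @param max_iter Iteration cap.
#' @return Tibble `protein`, `module` (integer module ids, 1 = largest).
#'   Deterministic for a fixed node ordering.
#' @examples
#' tri2 <- assemble_interactome(
#'   data.frame(protein_a = c("A", "B", "C", "X", "Y", "Z"),
#'              protein_b = c("B", "C", "A", "Y", "Z", "X")), NULL)
#' mcl_modules(tri2)
#' @export
mcl_modules <- function(net, inflation = 2, expansion = 2L, pruning = 1e-5,
                        max_iter = 100L) {
  if (inflation <= 1) {
    abort("inflation must be > 1", class = "peroxnet_bad_inflation")
  }
  if (expansion < 2L) {
    abort("expansion must be >= 2", class = "peroxnet_bad_inflation")
  }
  sg <- simple_graph(net)
  n <- igraph::vcount(sg)
  if (n == 0) {
    abort("cannot cluster an empty graph", class = "peroxnet_empty_graph")
  }
  A <- igraph::as_adjacency_matrix(sg, sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix")
  Matrix::diag(A) <- 1  # self-loops stabilise the iteration
  normalise <- function(M) M %*% Matrix::Diagonal(x = 1 / Matrix::colSums(M))
  M <- normalise(A)
  for (it in seq_len(max_iter)) {
    M2 <- M
    for (k in seq_len(expansion - 1L)) M2 <- M2 %*% M
    M2@x <- M2@x^inflation
    M2 <- normalise(M2)
    M2@x[M2@x < pruning] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- normalise(M2)
    if (max(abs(M2 - M)) < 1e-8) {
      M <- M2
      break
    }
    M <- M2
  }
  # rows with mass are attractors; the nonzeros in an attractor row are one module
  memb <- rep(NA_integer_, n)
  next_id <- 0L
  for (r in which(Matrix::rowSums(M) > 1e-6)) {
    members <- which(M[r, ] > 1e-6)
    if (!length(members)) next
    existing <- unique(memb[members])
    existing <- existing[!is.na(existing)]
    if (length(existing)) {
      memb[members] <- existing[1]
      if (length(existing) > 1) memb[memb %in% existing[-1]] <- existing[1]
    } else {
      next_id <- next_id + 1L
      memb[members] <- next_id
    }
  }
  if (anyNA(memb)) {  # numerically orphaned nodes become singletons
    for (i in which(is.na(memb))) {
      next_id <- next_id + 1L
      memb[i] <- next_id
    }
  }
  # relabel so module 1 is the largest, ties by first appearance
  sizes <- table(memb)
  order_ids <- as.integer(names(sort(sizes, decreasing = TRUE)))
  relabel <- match(memb, order_ids)
  tibble(protein = igraph::V(sg)$name, module = relabel) |>
    arrange(.data$module, .data$protein)
}
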