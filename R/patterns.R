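#' The canonical 17-pattern semantic relation graph
#'
#' Sixteen concept patterns are organized into four semantic neighborhoods of
#' four (1-4, 5-8, 9-12, 13-16). Every within-neighborhood pair is related at
#' typical strength except one strong pair per neighborhood ((1,2), (5,6),
#' (9,10), (13,14)). Four strong cross-neighborhood links ((2,11), (3,9),
#' (6,15), (7,13)) create indirect (mediated) relations. Pattern 17 is a
#' neutral baseline, unrelated to everything and carrying no inter-network
#' connections; each trial starts from it.
#'
#' Two prime types follow from this structure: a Type-I prime is strongly
#' related to one concept inside its own neighborhood (primes 1, 5, 10, 14); a
#' Type-II prime is strongly related to one concept in a different
#' neighborhood and only typically related within its own (primes 3, 11, 7,
#' 15). Indirect pairs are connected through a mediator strongly related to
#' both endpoints, with no direct relation between the endpoints (e.g. 1-11
#' via 2).
#'
#' @return An object of class `relation_graph`: a list of pair lists (each
#'   pair is `c(prime, target)`, indirect triples are
#'   `c(prime, target, mediator)`), the neighborhood partition, the pairs of
#'   mutually uncorrelated neighborhoods used for unrelated trials, and the
#'   baseline index.
#' @export
relation_graph <- function() {
  g <- list(
    n_patterns     = 17L,
    baseline_index = 17L,
    neighborhoods  = list(1:4, 5:8, 9:12, 13:16),
    strong_within_pairs = list(c(1L, 2L), c(5L, 6L), c(9L, 10L), c(13L, 14L)),
    strong_cross_pairs  = list(c(2L, 11L), c(3L, 9L), c(6L, 15L), c(7L, 13L)),
    typeI_direct_pairs  = list(c(1L, 2L), c(5L, 6L), c(10L, 9L), c(14L, 13L)),
    typeII_direct_pairs = list(c(3L, 9L), c(11L, 2L), c(7L, 13L), c(15L, 6L)),
    typeI_indirect_pairs  = list(c(1L, 11L, 2L), c(5L, 15L, 6L),
                                 c(10L, 3L, 9L), c(14L, 7L, 13L)),
    typeII_indirect_pairs = list(c(3L, 10L, 9L), c(11L, 1L, 2L),
                                 c(7L, 14L, 13L), c(15L, 5L, 6L)),
    # neighborhood index pairs with no correlations between any of their
    # members (cross links tie neighborhoods 1-3 and 2-4 together)
    unrelated_neighborhood_pairs = list(c(1L, 2L), c(1L, 4L), c(2L, 3L), c(3L, 4L))
  )
  # typical pairs: every within-neighborhood pair that is not the strong one
  typ <- list()
  for (nb in g$neighborhoods) {
    cmb <- utils::combn(nb, 2, simplify = FALSE)
    for (pr in cmb) {
      if (!any(vapply(g$strong_within_pairs,
                      function(s) all(sort(s) == sort(pr)), logical(1))))
        typ[[length(typ) + 1L]] <- as.integer(pr)
    }
  }
  g$typical_within_pairs <- typ
  class(g) <- "relation_graph"
  g
}

# flat table of declared relations: one row per pair, with strength label
relation_table <- function(graph) {
  rows <- rbind(
    do.call(rbind, lapply(graph$strong_within_pairs, function(x) c(x, 1L))),
    do.call(rbind, lapply(graph$strong_cross_pairs,  function(x) c(x, 1L))),
    do.call(rbind, lapply(graph$typical_within_pairs, function(x) c(x, 0L)))
  )
  data.frame(i = rows[, 1], j = rows[, 2],
             strength = ifelse(rows[, 3] == 1L, "strong", "typical"),
             stringsAsFactors = FALSE)
}

#' Construct the semantic memory patterns
#'
#' Builds binary patterns (one row per pattern) with exactly `round(p * N)`
#' active neurons each and an exactly realized overlap structure: every
#' declared relation shares `round(frac * n_active)` active neurons (strong
#' relations a fraction 0.1 of the active set, typical relations 0.066, i.e.
#' 3 and 2 neurons at N = 500, p = 0.06), and every undeclared pair shares
#' none. Shared neurons are dedicated to their pair, so no neuron belongs to
#' more than two patterns and undeclared correlations are exactly zero (two
#' disjoint equally sparse binary patterns have Pearson correlation
#' `-p/(1-p)`, a small negative bias).
#'
#' @param N Number of neurons.
#' @param p Sparseness (fraction of active neurons per pattern).
#' @param graph A `relation_graph` (defaults to the canonical 17-pattern one).
#' @param strong_frac,typical_frac Overlap fractions for the two relation
#'   strengths, as fractions of the active set.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An object of class `pattern_set`: list with `patterns`
#'   (n_patterns x N integer 0/1 matrix), `p`, `n_active`, `baseline_index`,
#'   `graph`, and `relations` (the declared pair table with realized overlap
#'   counts).
#' @export
make_semantic_patterns <- function(N = 500, p = 0.06, graph = relation_graph(),
                                   strong_frac = 0.1, typical_frac = 0.066,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_pat <- graph$n_patterns
  n_active <- as.integer(round(p * N))
  rel <- relation_table(graph)
  rel$overlap <- as.integer(round(ifelse(rel$strength == "strong",
                                         strong_frac, typical_frac) * n_active))

  sets <- vector("list", n_pat)
  for (k in seq_len(n_pat)) sets[[k]] <- integer(0)
  pool <- sample.int(N)
  take <- function(n) {
    if (n > length(pool))
      stop("infeasible allocation: neuron pool exhausted", call. = FALSE)
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  # dedicated shared neurons per declared relation
  for (r in seq_len(nrow(rel))) {
    i <- rel$i[r]; j <- rel$j[r]
    shared <- take(rel$overlap[r])
    sets[[i]] <- c(sets[[i]], shared)
    sets[[j]] <- c(sets[[j]], shared)
  }
  # disjoint fill to the target active count
  for (k in seq_len(n_pat)) {
    need <- n_active - length(sets[[k]])
    if (need < 0)
      stop(sprintf(
        "infeasible allocation: pattern %d requires %d shared neurons but only %d active slots",
        k, length(sets[[k]]), n_active), call. = FALSE)
    sets[[k]] <- c(sets[[k]], take(need))
  }
  patterns <- matrix(0L, n_pat, N)
  for (k in seq_len(n_pat)) patterns[k, sets[[k]]] <- 1L

  structure(list(
    patterns = patterns, p = p, n_active = n_active,
    baseline_index = graph$baseline_index, graph = graph, relations = rel
  ), class = "pattern_set")
}

#' Construct the lexical word patterns
#'
#' All word patterns are mutually disjoint (no lexical/phonological relations
#' between experimental words), each with `round(p * N)` active neurons.
#'
#' @param N Number of neurons.
#' @param p Sparseness.
#' @param n_patterns Number of patterns (17: 16 words plus the neutral
#'   baseline).
#' @param seed Optional integer seed.
#' @return A `pattern_set` (with `graph = NULL` and no declared relations).
#' @export
make_lexical_patterns <- function(N = 500, p = 0.04, n_patterns = 17,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_active <- as.integer(round(p * N))
  if (n_patterns * n_active > N)
    stop(sprintf("infeasible allocation: %d disjoint patterns of %d neurons exceed N = %d",
                 n_patterns, n_active, N), call. = FALSE)
  pool <- sample.int(N)
  patterns <- matrix(0L, n_patterns, N)
  for (k in seq_len(n_patterns)) {
    idx <- pool[seq_len(n_active)]
    pool <- pool[-seq_len(n_active)]
    patterns[k, idx] <- 1L
  }
  structure(list(
    patterns = patterns, p = p, n_active = n_active,
    baseline_index = as.integer(n_patterns), graph = NULL, relations = NULL
  ), class = "pattern_set")
}

#' Pairwise overlap counts of a pattern set
#'
#' @param ps A `pattern_set`.
#' @return Integer matrix: entry (i, j) is the number of active neurons
#'   shared by patterns i and j (diagonal: active-set sizes).
#' @export
pattern_overlaps <- function(ps) {
  o <- ps$patterns %*% t(ps$patterns)
  storage.mode(o) <- "integer"
  o
}

#' Validate the invariants of a pattern set
#'
#' Checks equal active counts, exact declared overlaps, zero undeclared
#' overlaps, and baseline isolation. Errors on the first violation.
#'
#' @param ps A `pattern_set`.
#' @return `ps`, invisibly.
#' @export
validate_pattern_set <- function(ps) {
  n_pat <- nrow(ps$patterns)
  counts <- rowSums(ps$patterns)
  if (!all(counts == ps$n_active))
    stop("active-count invariant violated for pattern(s): ",
         paste(which(counts != ps$n_active), collapse = ", "))
  ov <- pattern_overlaps(ps)
  declared <- matrix(0L, n_pat, n_pat)
  if (!is.null(ps$relations)) {
    for (r in seq_len(nrow(ps$relations))) {
      i <- ps$relations$i[r]; j <- ps$relations$j[r]
      declared[i, j] <- declared[j, i] <- ps$relations$overlap[r]
    }
  }
  diag(declared) <- ps$n_active
  if (!all(ov == declared)) {
    bad <- which(ov != declared, arr.ind = TRUE)[1, ]
    stop(sprintf("overlap invariant violated for pair (%d, %d): declared %d, realized %d",
                 bad[1], bad[2], declared[bad[1], bad[2]], ov[bad[1], bad[2]]))
  }
  b <- ps$baseline_index
  if (any(ov[b, -b] != 0L))
    stop("baseline pattern shares active neurons with another pattern")
  invisible(ps)
}

#' Sparse-coding covariance (Hopfield) connectivity
#'
#' The standard covariance prescription for sparse binary patterns:
#' \deqn{J_{ij} = \frac{1}{N p (1-p)} \sum_\mu (\xi_i^\mu - p)(\xi_j^\mu - p)}
#' with zero diagonal. Storing a pattern makes it a fixed point of the
#' noiseless, depression-free rate dynamics.
#'
#' @param ps A `pattern_set`.
#' @param p Sparseness used in the rule (defaults to the set's own).
#' @return A symmetric N x N matrix with zero diagonal.
#' @export
hopfield_weights <- function(ps, p = ps$p) {
  C <- ps$patterns - p                     # n_pat x N
  N <- ncol(C)
  J <- crossprod(C) / (N * p * (1 - p))
  diag(J) <- 0
  J
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set: %d patterns x %d neurons, p = %g (%d active), baseline = %d>\n",
              nrow(x$patterns), ncol(x$patterns), x$p, x$n_active, x$baseline_index))
  invisible(x)
}

#' Write a pattern set to a JSON file
#'
#' Serializes the binary matrix and metadata to plain JSON; [read_pattern_set()]
#' restores it bit-exactly.
#'
#' @param ps A `pattern_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_set <- function(ps, path) {
  obj <- list(
    patterns = unclass(ps$patterns), p = ps$p, n_active = ps$n_active,
    baseline_index = ps$baseline_index,
    relations = ps$relations,
    canonical_graph = identical(ps$graph, relation_graph())
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a pattern set written by [write_pattern_set()]
#'
#' @param path JSON file path.
#' @return A `pattern_set`. The canonical relation graph is reattached when
#'   the stored set declared one.
#' @export
read_pattern_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pat <- as.matrix(obj$patterns)
  storage.mode(pat) <- "integer"
  rel <- obj$relations
  if (!is.null(rel) && nrow(rel) > 0) {
    rel <- as.data.frame(rel)
  } else rel <- NULL
  structure(list(
    patterns = pat, p = obj$p, n_active = as.integer(obj$n_active),
    baseline_index = as.integer(obj$baseline_index),
    graph = if (isTRUE(obj$canonical_graph)) relation_graph() else NULL,
    relations = rel
  ), class = "pattern_set")
}
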