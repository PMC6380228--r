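#' Levenshtein edit distance
#'
#' Unit-cost edit distance: the length of the shortest sequence of
#' single-character insertions, deletions, or substitutions transforming
#' `s` into `t`. Computed on the raw strings -- case differences are
#' edits like any other.
#'
#' @param s,t Character vectors, recycled to a common length.
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("age", "age")        # 0
#' levenshtein("abc", "")           # 3
#' levenshtein("weight", "weight_kg")
levenshtein <- function(s, t) {
  n <- max(length(s), length(t))
  s <- rep_len(as.character(s), n)
  t <- rep_len(as.character(t), n)
  vapply(seq_len(n), function(i) {
    as.integer(utils::adist(s[[i]], t[[i]])[1L, 1L])
  }, integer(1))
}

#' Pairwise similarity matrix of attribute names
#'
#' Entry (i, j) is the negated Levenshtein distance between names i and
#' j -- the similarity convention used by affinity propagation, where
#' larger means more alike. The matrix is symmetric with a zero
#' diagonal.
#'
#' @param names Character vector of unique names.
#' @return A numeric `length(names)` x `length(names)` matrix with
#'   `names` as dimnames.
#' @export
similarity_matrix <- function(names) {
  if (anyDuplicated(names)) {
    stop("names must be unique", call. = FALSE)
  }
  s <- -utils::adist(names, names)
  dimnames(s) <- list(names, names)
  s
}

#' Affinity propagation clustering
#'
#' Exemplar-based clustering by message passing (responsibilities and
#' availabilities) over a similarity matrix. Unlike k-means or
#' k-medoids, the number of clusters is not fixed upfront: it emerges
#' from the shared `preference` placed on the diagonal, and each cluster
#' is represented by one of its own members, the *exemplar*.
#'
#' A deterministic, seeded jitter (about 1e-8 of the similarity scale)
#' breaks ties so that runs with the same inputs, parameters and seed
#' give identical clusterings. Convergence means the exemplar set is
#' stable for `conv_iter` consecutive iterations; if `max_iter` passes
#' without that, the current solution is returned with
#' `converged = FALSE`.
#'
#' @param s Square similarity matrix (larger = more similar).
#' @param preference Shared diagonal value controlling how readily
#'   points become exemplars; default is the median of the off-diagonal
#'   similarities.
#' @param damping Update damping factor in `[0.5, 1)`.
#' @param max_iter Maximum number of message-passing iterations.
#' @param conv_iter Iterations the exemplar set must stay unchanged to
#'   declare convergence.
#' @param seed Integer seed for the tie-breaking jitter.
#' @return A list: `labels` (exemplar index for every point),
#'   `exemplars` (indices), `iterations`, `converged`.
#' @export
affinity_propagation <- function(s, preference = NULL, damping = 0.5,
                                 max_iter = 1000L, conv_iter = 15L,
                                 seed = 1L) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  if (damping < 0.5 || damping >= 1) {
    stop("damping must be in [0.5, 1)", call. = FALSE)
  }
  n <- nrow(s)
  if (n == 1L) {
    return(list(labels = 1L, exemplars = 1L, iterations = 0L,
                converged = TRUE))
  }
  if (is.null(preference)) {
    preference <- median(s[row(s) != col(s)])
  }
  s <- s * 1.0
  diag(s) <- preference
  jitter <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    matrix(rnorm(n * n), n, n)
  })
  s <- s + jitter * 1e-8 * (max(abs(s)) + 1)

  a <- r <- matrix(0, n, n)
  e_hist <- matrix(FALSE, n, conv_iter)
  converged <- FALSE
  it <- 0L
  rows <- seq_len(n)
  while (it < max_iter) {
    it <- it + 1L
    as_mat <- a + s
    i1 <- max.col(as_mat, ties.method = "first")
    first <- as_mat[cbind(rows, i1)]
    as_mat[cbind(rows, i1)] <- -Inf
    second <- as_mat[cbind(rows, max.col(as_mat, ties.method = "first"))]
    r_new <- s - first
    r_new[cbind(rows, i1)] <- s[cbind(rows, i1)] - second
    r <- damping * r + (1 - damping) * r_new

    rp <- pmax(r, 0)
    diag(rp) <- diag(r)
    cs <- colSums(rp)
    a_new <- pmin(matrix(cs, n, n, byrow = TRUE) - rp, 0)
    diag(a_new) <- cs - diag(rp)      # sum over i' != k of max(0, r[i', k])
    a <- damping * a + (1 - damping) * a_new

    e <- (diag(a) + diag(r)) > 0
    e_hist[, (it - 1L) %% conv_iter + 1L] <- e
    if (it >= conv_iter && any(e)) {
      stable <- all(e_hist == e_hist[, 1L])
      if (stable) { converged <- TRUE; break }
    }
  }
  exemplars <- which((diag(a) + diag(r)) > 0)
  if (!length(exemplars)) {
    exemplars <- which.max(diag(a) + diag(r))
  }
  labels <- exemplars[max.col(s[, exemplars, drop = FALSE],
                              ties.method = "first")]
  labels[exemplars] <- exemplars
  list(labels = labels, exemplars = exemplars, iterations = it,
       converged = converged)
}

#' Cluster attribute names by edit-distance similarity
#'
#' Builds the negated-Levenshtein similarity matrix over the names and
#' partitions them with [affinity_propagation()]. Every name lands in
#' exactly one cluster and every cluster's exemplar is one of its
#' members. Distances are computed on the raw strings by default; with
#' `casefold = TRUE` similarities are computed on lower-cased copies
#' while the reported names keep their original spelling.
#'
#' @param names Character vector of unique attribute names.
#' @param preference,damping,max_iter,conv_iter,seed Passed to
#'   [affinity_propagation()]; `preference = NULL` uses the median
#'   off-diagonal similarity.
#' @param casefold Lower-case names before computing distances.
#' @return A `cluster_set`: list with `clusters` (tibble `cluster`,
#'   `exemplar`, `member`, `distance` to the exemplar), `parameters`,
#'   and `converged`.
#' @export
#' @examples
#' cs <- cluster_names(c("Submitted by", "Submitter", "Submitters"))
#' cs$clusters
cluster_names <- function(names, preference = NULL, damping = 0.5,
                          max_iter = 1000L, conv_iter = 15L, seed = 1L,
                          casefold = FALSE) {
  if (!length(names)) {
    stop("need at least one name", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("names must be unique", call. = FALSE)
  }
  key <- if (casefold) tolower(names) else names
  # names identical at distance 0 (case collisions under casefold) are
  # merged up front: message passing runs over distinct keys only, so
  # distance-0 pairs can never land in different clusters
  ukey <- unique(key)
  key_of <- match(key, ukey)
  s <- -utils::adist(ukey, ukey)
  fit <- affinity_propagation(s, preference = preference, damping = damping,
                              max_iter = max_iter, conv_iter = conv_iter,
                              seed = seed)
  labels <- fit$labels[key_of]
  exemplar <- names[match(ukey[labels], key)]
  dist_to_ex <- -s[cbind(key_of, labels)]
  clusters <- tibble::tibble(
    cluster = match(labels, sort(unique(labels))),
    exemplar = exemplar,
    member = names,
    distance = as.integer(round(dist_to_ex)))
  clusters <- clusters[order(clusters$cluster, clusters$distance,
                             clusters$member), ]
  structure(list(clusters = clusters,
                 parameters = list(preference = preference %||% "median",
                                   damping = damping, max_iter = max_iter,
                                   conv_iter = conv_iter, seed = seed,
                                   casefold = casefold),
                 converged = fit$converged),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  k <- length(unique(x$clusters$cluster))
  cat(sprintf("<cluster_set> %d names in %d clusters%s\n",
              nrow(x$clusters), k,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Rank attribute names by frequency of use
#'
#' Counts, for every (trimmed) attribute name, how many records use it
#' and how many attribute occurrences carry it; ranked by records
#' descending, ties broken lexicographically. Record counts are the
#' basis for concept-level tallies; occurrence counts are reported
#' alongside.
#'
#' @param corpus A [sample_corpus()].
#' @return A tibble `name`, `n_records`, `n_occurrences`.
#' @export
rank_names_by_use <- function(corpus) {
  stopifnot(inherits(corpus, "sample_corpus"))
  if (!nrow(corpus$attributes)) {
    return(tibble::tibble(name = character(), n_records = integer(),
                          n_occurrences = integer()))
  }
  tibble::tibble(name = trimws(corpus$attributes$name),
                 accession = corpus$attributes$accession) |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(n_records = dplyr::n_distinct(.data$accession),
                     n_occurrences = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_records), .data$name)
}
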