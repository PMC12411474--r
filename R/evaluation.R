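#' Blau's diversity index
#'
#' `1 - sum(p_i^2)` over category proportions: 0 when every element falls
#' in one category, approaching 1 under maximal diversity (for k equal
#' categories the value is `1 - 1/k`).
#'
#' @param category_counts Non-negative counts, total > 0.
#' @return A number in `[0, 1)`.
#' @examples
#' blau_index(c(31, 1))   # 0.0605...
#' @export
blau_index <- function(category_counts) {
  if (any(category_counts < 0)) stop("counts must be non-negative")
  total <- sum(category_counts)
  if (total <= 0) stop("all-zero category counts")
  p <- category_counts / total
  1 - sum(p^2)
}

set_key <- function(s) {
  if (length(s)) paste(sort(unique(s)), collapse = "+") else "(none)"
}

#' Distinct recommendation sets
#'
#' Categorizes a recommender's per-patient drug sets by exact set equality
#' (the empty set is its own category) and returns the category counts —
#' the categories over which recommendation diversity is measured.
#'
#' @param output A [system_output()].
#' @return Named integer vector of counts (sums to the cohort size).
#' @export
distinct_recommendation_sets <- function(output) {
  keys <- vapply(output$sets, set_key, character(1))
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  sort(counts, decreasing = TRUE)
}

#' Overlap concordance between two recommenders
#'
#' The proportion of patients for whom the two systems share at least one
#' recommended drug.  With the `favorable_only` denominator the proportion
#' is taken over patients for whom the first system recommended at least
#' one drug; with `all_patients` over the whole cohort.
#'
#' @param a,b [system_output()] objects over the same cohort; `a` is the
#'   system whose favorable patients define the restricted denominator.
#' @param denominator `"all_patients"` or `"favorable_only"`.
#' @return Percentage in `[0, 100]`.
#' @export
overlap_concordance <- function(a, b,
                                denominator = c("all_patients",
                                                "favorable_only")) {
  denominator <- match.arg(denominator)
  if (!identical(sort(names(a$sets)), sort(names(b$sets))))
    stop("systems cover different cohorts")
  ids <- names(a$sets)
  overlap <- vapply(ids, function(id)
    length(intersect(a$sets[[id]], b$sets[[id]])) > 0, logical(1))
  if (denominator == "favorable_only") {
    fav <- vapply(ids, function(id) length(a$sets[[id]]) > 0, logical(1))
    if (!any(fav)) stop("no favorable patients for system '", a$system_id, "'")
    100 * sum(overlap[fav]) / sum(fav)
  } else {
    100 * sum(overlap) / length(ids)
  }
}

#' Pharmacological distance scheme
#'
#' Distance between two drug profiles is a weighted sum of mismatches:
#' `w_target` per neurotransmitter target in the symmetric difference,
#' `w_mode` per mode of action in the symmetric difference, `w_family` when
#' the chemical families differ, and `w_relation` per step separating the
#' drugs in the enantiomer/prodrug/salt relation graph (drugs with
#' identical pharmacology but distinct chemistry, e.g. an enantiomer pair,
#' sit at distance `w_relation`).  The reserved `no_treatment` element is at
#' the fixed maximum from every active drug.  The default weights
#' (10/2/5/1, maximum 33) are solved exactly from the five published anchor
#' distances from methylphenidate: dexmethylphenidate 1, bupropion 7,
#' atomoxetine 15, guanfacine 19, no treatment 33.
#'
#' @param w_target,w_mode,w_family,w_relation Component weights.
#' @param max_distance Distance to `no_treatment`; also the scheme ceiling.
#' @export
distance_scheme <- function(w_target = 10, w_mode = 2, w_family = 5,
                            w_relation = 1, max_distance = 33) {
  list(w_target = w_target, w_mode = w_mode, w_family = w_family,
       w_relation = w_relation, max_distance = max_distance)
}

relation_steps <- function(profiles) {
  # undirected relation graph over drugs; BFS all-pairs shortest paths
  drugs <- names(profiles)
  adj <- setNames(vector("list", length(drugs)), drugs)
  for (d in drugs)
    for (other in unname(profiles[[d]]$relations))
      if (other %in% drugs) {
        adj[[d]] <- union(adj[[d]], other)
        adj[[other]] <- union(adj[[other]], d)
      }
  steps <- matrix(Inf, length(drugs), length(drugs),
                  dimnames = list(drugs, drugs))
  diag(steps) <- 0
  for (d in drugs) {
    frontier <- d; dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      frontier <- setdiff(unique(unlist(adj[frontier])),
                          drugs[is.finite(steps[d, ])])
      steps[d, frontier] <- dist
    }
  }
  steps
}

#' Build the drug distance matrix
#'
#' @param profiles Named list of drug profiles (see
#'   [default_drug_profiles()]); must include `no_treatment`.
#' @param scheme A [distance_scheme()].
#' @return A symmetric `dist`-free numeric matrix with zero diagonal,
#'   entries in `[0, max_distance]`.  Errors if the profiles and weights
#'   produce any entry above the ceiling.
#' @examples
#' D <- build_distance_matrix()
#' D["methylphenidate", "atomoxetine"]       # 15
#' D["methylphenidate", "no_treatment"]      # 33
#' @export
build_distance_matrix <- function(profiles = default_drug_profiles(),
                                  scheme = distance_scheme()) {
  if (!"no_treatment" %in% names(profiles))
    stop("profiles must include the reserved 'no_treatment' element")
  drugs <- names(profiles)
  steps <- relation_steps(profiles)
  D <- matrix(0, length(drugs), length(drugs),
              dimnames = list(drugs, drugs))
  for (i in seq_along(drugs)) for (j in seq_along(drugs)) {
    if (j <= i) next
    a <- drugs[i]; b <- drugs[j]
    if (a == "no_treatment" || b == "no_treatment") {
      D[i, j] <- D[j, i] <- scheme$max_distance
      next
    }
    pa <- profiles[[a]]; pb <- profiles[[b]]
    rel <- steps[a, b]
    d <- scheme$w_target * length(c(setdiff(pa$targets, pb$targets),
                                    setdiff(pb$targets, pa$targets))) +
         scheme$w_mode * length(c(setdiff(pa$modes, pb$modes),
                                  setdiff(pb$modes, pa$modes))) +
         scheme$w_family * (pa$family != pb$family) +
         scheme$w_relation * (if (is.finite(rel)) rel else 0)
    if (d > scheme$max_distance)
      stop("distance ", d, " between '", a, "' and '", b,
           "' exceeds the scheme maximum ", scheme$max_distance)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Distance between two recommendation sets
#'
#' Modified-Hausdorff average: the mean of the two directed mean-of-minima
#' distances between the sets under a drug distance matrix.  Empty sets are
#' replaced by `{no_treatment}`, so "no recommendation" sits at the scheme
#' maximum from any active drug and at 0 from another empty set.
#'
#' @param set_a,set_b Character vectors of drug codes.
#' @param matrix Drug distance matrix from [build_distance_matrix()].
#' @return Non-negative number; 0 iff the sets are equal as sets.
#' @export
recset_distance <- function(set_a, set_b, matrix = build_distance_matrix()) {
  a <- if (length(set_a)) unique(set_a) else "no_treatment"
  b <- if (length(set_b)) unique(set_b) else "no_treatment"
  missing <- setdiff(c(a, b), rownames(matrix))
  if (length(missing))
    stop("drug absent from distance matrix: ", paste(missing, collapse = ", "))
  h_ab <- mean(vapply(a, function(x) min(matrix[x, b]), numeric(1)))
  h_ba <- mean(vapply(b, function(y) min(matrix[y, a]), numeric(1)))
  (h_ab + h_ba) / 2
}

#' System-level distance matrix
#'
#' Entry (s, t) is the mean over the cohort of the per-patient
#' recommendation-set distance between systems s and t.
#'
#' @param outputs List of [system_output()] objects over one cohort.
#' @param matrix Drug distance matrix.
#' @return Symmetric matrix over system ids with zero diagonal.
#' @export
system_distance_matrix <- function(outputs, matrix = build_distance_matrix()) {
  if (length(outputs) < 2) stop("need at least two systems")
  ids <- vapply(outputs, `[[`, character(1), "system_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  cohorts <- lapply(outputs, function(o) sort(names(o$sets)))
  if (!all(vapply(cohorts, identical, logical(1), y = cohorts[[1]])))
    stop("systems cover different cohorts")
  cases <- cohorts[[1]]
  M <- base::matrix(0, length(outputs), length(outputs),
                    dimnames = list(ids, ids))
  for (i in seq_along(outputs)) for (j in seq_along(outputs)) {
    if (j <= i) next
    d <- mean(vapply(cases, function(cid)
      recset_distance(outputs[[i]]$sets[[cid]], outputs[[j]]$sets[[cid]],
                      matrix), numeric(1)))
    M[i, j] <- M[j, i] <- d
  }
  M
}

#' UPGMA dendrogram over recommender systems
#'
#' Average-linkage agglomerative clustering with deterministic tie-breaking
#' (among equally close pairs, the lexicographically smallest pair of
#' cluster representatives merges first).  Merge heights are non-decreasing
#' (the UPGMA tree is ultrametric).
#'
#' @param dist Symmetric distance matrix with labelled rows/columns.
#' @return An object of classes `upgma_tree` and `hclust` (usable with
#'   `plot()`, `stats::cutree()`, `ape::as.phylo()`), with an extra
#'   `newick` component holding the Newick serialization (branch lengths
#'   from merge heights).
#' @examples
#' d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma_tree(d)$height   # 1, 10
#' @export
upgma_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 2) stop("need at least two systems")
  if (is.null(rownames(dist)))
    rownames(dist) <- colnames(dist) <- paste0("S", seq_len(nrow(dist)))
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(dist)
  n <- length(labels)
  # active clusters: id (merge-matrix convention), members, representative
  cl <- lapply(seq_len(n), function(i)
    list(id = -i, members = i, rep = labels[i], size = 1L))
  D <- dist
  merge <- base::matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(cl)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      d <- D[i, j]
      pair <- sort(c(cl[[i]]$rep, cl[[j]]$rep))
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(i = i, j = j, d = d, pair = pair)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- c(cl[[i]]$id, cl[[j]]$id)
    height[step] <- best$d
    newc <- list(id = step,
                 members = c(cl[[i]]$members, cl[[j]]$members),
                 rep = min(cl[[i]]$rep, cl[[j]]$rep),
                 size = cl[[i]]$size + cl[[j]]$size)
    keep <- setdiff(seq_len(m), c(i, j))
    newD <- base::matrix(0, length(keep) + 1, length(keep) + 1)
    if (length(keep)) {
      newD[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
      newD[length(keep) + 1, seq_along(keep)] <-
        newD[seq_along(keep), length(keep) + 1] <-
        (cl[[i]]$size * D[i, keep] + cl[[j]]$size * D[j, keep]) /
          (cl[[i]]$size + cl[[j]]$size)
    }
    cl <- c(cl[keep], list(newc))
    D <- newD
  }
  ord <- integer(0)
  walk <- function(id) {
    if (id < 0) ord <<- c(ord, -id)
    else { walk(merge[id, 1]); walk(merge[id, 2]) }
  }
  walk(n - 1)
  hc <- structure(list(merge = merge, height = height, order = ord,
                       labels = labels, method = "average",
                       call = match.call(), dist.method = "pharmacological"),
                  class = c("upgma_tree", "hclust"))
  hc$newick <- ape::write.tree(ape::as.phylo(stats::as.hclust(hc)))
  hc
}

#' @export
as.hclust.upgma_tree <- function(x, ...) {
  x$newick <- NULL
  class(x) <- "hclust"
  x
}

#' Write a dendrogram to a Newick file
#'
#' @param tree An [upgma_tree()].
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}

#' Recommender comparison summary
#'
#' One row per system: distinct-set count, Blau index (two decimals, the
#' reporting precision used for diversity), and per-drug recommendation
#' percentages (one decimal).
#'
#' @param outputs List of [system_output()] objects over one cohort.
#' @param drugs Drug codes for the percentage columns (default: every drug
#'   appearing in any output).
#' @return A data.frame, systems as rows.
#' @export
evaluation_summary <- function(outputs, drugs = NULL) {
  if (is.null(drugs))
    drugs <- sort(unique(unlist(lapply(outputs, function(o)
      unlist(o$sets)))))
  rows <- lapply(outputs, function(o) {
    counts <- distinct_recommendation_sets(o)
    n <- length(o$sets)
    pct <- vapply(drugs, function(d)
      round(100 * mean(vapply(o$sets, function(s) d %in% s, logical(1))), 1),
      numeric(1))
    cbind(data.frame(system = o$system_id,
                     n_distinct = length(counts),
                     blau = round(blau_index(counts), 2)),
          as.data.frame(as.list(pct)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
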