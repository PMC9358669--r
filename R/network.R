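#' Modified-cosine similarity of two MS/MS spectra
#'
#' Fragment intensities are square-root transformed and L2-normalized.
#' Candidate fragment pairs match either directly (|mzA - mzB| <= frag_tol)
#' or through the precursor-difference channel
#' (|mzA - mzB - (precA - precB)| <= frag_tol), so that analogs differing by
#' one residue still align. A one-to-one pairing is chosen greedily by
#' decreasing intensity product (deterministic tie-break by peak index); the
#' score is the sum of paired normalized-intensity products. With
#' `method = "exact"` the optimal pairing is found by exhaustive branch
#' search, practical for small spectra.
#'
#' @param a,b MS2 [ms_spectrum()] objects with precursor m/z.
#' @param frag_tol Fragment tolerance in Da.
#' @param min_matched Pairings below this count score 0 (count still reported).
#' @param method `"greedy"` (default, GNPS-style) or `"exact"`.
#' @return List with `score` in [0, 1] and `n_matched`.
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02, min_matched = 6L,
                            method = c("greedy", "exact")) {
  method <- match.arg(method)
  if (!length(a$mz) || !length(b$mz)) return(list(score = 0, n_matched = 0L))
  if (is.na(a$precursor_mz) || is.na(b$precursor_mz)) {
    stop("modified cosine requires precursor m/z on both spectra")
  }
  # canonical operand order so score(a, b) == score(b, a) bit-for-bit
  if (b$precursor_mz < a$precursor_mz ||
      (b$precursor_mz == a$precursor_mz && b$scan_id < a$scan_id)) {
    tmp <- a; a <- b; b <- tmp
  }
  wa <- sqrt(a$intensity); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(b$intensity); wb <- wb / sqrt(sum(wb^2))
  dprec <- a$precursor_mz - b$precursor_mz
  cand <- list()
  for (i in seq_along(a$mz)) {
    d <- a$mz[i] - b$mz
    hit <- which(abs(d) <= frag_tol | abs(d - dprec) <= frag_tol)
    for (j in hit) {
      cand[[length(cand) + 1L]] <- c(i, j, wa[i] * wb[j])
    }
  }
  if (!length(cand)) return(list(score = 0, n_matched = 0L))
  cand <- do.call(rbind, cand)
  if (method == "greedy") {
    o <- order(-cand[, 3], cand[, 1], cand[, 2])
    cand <- cand[o, , drop = FALSE]
    used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
    score <- 0; nm <- 0L
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      score <- score + cand[r, 3]; nm <- nm + 1L
    }
  } else {
    res <- .best_pairing(cand)
    score <- res$score; nm <- res$n
  }
  if (nm < min_matched) score <- 0
  list(score = min(score, 1), n_matched = nm)
}

# exact maximum-weight one-to-one pairing by depth-first branch search
.best_pairing <- function(cand) {
  o <- order(-cand[, 3])
  cand <- cand[o, , drop = FALSE]
  n <- nrow(cand)
  best <- list(score = 0, n = 0L)
  suffix <- rev(cumsum(rev(cand[, 3])))
  recurse <- function(r, used_a, used_b, score, count) {
    if (score > best$score) best <<- list(score = score, n = count)
    if (r > n || score + suffix[r] <= best$score) return()
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!(i %in% used_a) && !(j %in% used_b)) {
      recurse(r + 1L, c(used_a, i), c(used_b, j), score + cand[r, 3], count + 1L)
    }
    recurse(r + 1L, used_a, used_b, score, count)
  }
  recurse(1L, integer(0), integer(0), 0, 0L)
  best
}

#' Construct a molecular network
#'
#' @param nodes `data.frame` with at least an `id` column.
#' @param edges `data.frame` with `from`, `to`, `type`, `score` (may be empty).
#' @return List of class `"molecular_network"`.
#' @export
molecular_network <- function(nodes, edges) {
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    bad <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(bad)) stop("edge endpoint not in nodes: ", bad[[1]])
  }
  structure(list(nodes = nodes, edges = edges), class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("<molecular_network> %d nodes, %d edges (%d msms, %d binding)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$type == "msms"), sum(x$edges$type == "binding")))
  invisible(x)
}

#' Build the combined molecular/binding network
#'
#' Metabolite features with MS/MS spectra are connected by modified-cosine
#' edges (kept when score >= `score_threshold` and at least `min_matched`
#' fragments pair, and when the edge ranks within both endpoints' `top_k`
#' strongest edges). One protein node is added, with a typed binding edge per
#' complex match annotated with the mass shift and co-elution correlation.
#'
#' @param metabolite_features A metabolite feature table.
#' @param spectra Named list of MS2 [ms_spectrum()] objects, names = scan ids
#'   (as referenced in the feature table's `ms2` column).
#' @param matches Match table from [match_complexes()] (may be `NULL`).
#' @param score_threshold Minimum modified-cosine score for an msms edge.
#' @param min_matched Minimum matched fragments for an msms edge.
#' @param frag_tol Fragment tolerance (Da).
#' @param top_k Per-node cap on msms edges (edge kept only if within both
#'   endpoints' top_k; ties broken by lower partner id).
#' @param protein_node Id of the protein node.
#' @param method Pairing method for [modified_cosine()].
#' @return A `molecular_network`.
#' @export
build_network <- function(metabolite_features, spectra, matches = NULL,
                          score_threshold = 0.7, min_matched = 6L,
                          frag_tol = 0.02, top_k = 10L,
                          protein_node = "protein", method = "greedy") {
  ft <- metabolite_features
  nodes <- data.frame(
    id = c(ft$id, protein_node),
    type = c(rep("metabolite", nrow(ft)), "protein"),
    mass = c(ft$mass_value, if (!is.null(matches) && nrow(matches)) matches$apo_mass[1] else NA_real_),
    rt = c(ft$rt_apex, NA_real_),
    abundance = c(ft$area, NA_real_),
    stringsAsFactors = FALSE
  )
  rep_spec <- lapply(seq_len(nrow(ft)), function(i) {
    ids <- ft$ms2[[i]]
    ids <- ids[ids %in% names(spectra)]
    if (!length(ids)) return(NULL)
    cands <- spectra[ids]
    tic <- vapply(cands, function(s) sum(s$intensity), numeric(1))
    cands[[which.max(tic)]]
  })
  edges <- list()
  with_spec <- which(!vapply(rep_spec, is.null, logical(1)))
  if (length(with_spec) > 1L) {
    for (ii in seq_along(with_spec)) {
      for (jj in seq_along(with_spec)) {
        if (jj <= ii) next
        i <- with_spec[ii]; j <- with_spec[jj]
        mc <- modified_cosine(rep_spec[[i]], rep_spec[[j]], frag_tol = frag_tol,
                              min_matched = min_matched, method = method)
        if (mc$score >= score_threshold && mc$n_matched >= min_matched) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = ft$id[i], to = ft$id[j], type = "msms",
            score = mc$score, n_matched = mc$n_matched,
            delta_mass = NA_real_, coelution = NA_real_,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), type = character(0),
               score = numeric(0), n_matched = integer(0),
               delta_mass = numeric(0), coelution = numeric(0),
               stringsAsFactors = FALSE)
  if (nrow(edges) && is.finite(top_k)) {
    keep <- rep(TRUE, nrow(edges))
    for (v in unique(c(edges$from, edges$to))) {
      touching <- which(edges$from == v | edges$to == v)
      if (length(touching) <= top_k) next
      partner <- ifelse(edges$from[touching] == v, edges$to[touching],
                        edges$from[touching])
      o <- touching[order(-edges$score[touching], partner)]
      keep[o[-seq_len(top_k)]] <- FALSE
    }
    edges <- edges[keep, , drop = FALSE]
  }
  if (!is.null(matches) && nrow(matches)) {
    bind <- data.frame(
      from = protein_node, to = matches$metabolite_feature_id, type = "binding",
      score = matches$coelution, n_matched = NA_integer_,
      delta_mass = matches$delta_mass, coelution = matches$coelution,
      stringsAsFactors = FALSE
    )
    bind <- bind[bind$to %in% nodes$id & !duplicated(bind$to), , drop = FALSE]
    edges <- rbind(edges, bind)
  }
  rownames(edges) <- NULL
  molecular_network(nodes, edges)
}

#' Summarize connected components of a molecular network
#'
#' @param network A `molecular_network`.
#' @return `data.frame` with component id, size and number of binding edges.
#' @export
network_components <- function(network) {
  g <- as_igraph(network)
  comp <- igraph::components(g)
  member <- comp$membership
  is_binding <- network$edges$type == "binding"
  bind_to <- network$edges$to[is_binding]
  data.frame(
    component = seq_len(comp$no),
    size = as.integer(comp$csize),
    n_binding = vapply(seq_len(comp$no), function(k) {
      sum(member[bind_to] == k)
    }, integer(1))
  )
}
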