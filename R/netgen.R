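# Synthetic annotated-network generator.
#
# Produces XGMML networks shaped like IIS/InnateDB exports: nodes carry a
# single-valued "Selected CC" attribute sampled from a compartment
# distribution, a configurable fraction carries unknown or empty labels
# (exercising the cytosol fallback), and a fraction gets a multivalued
# "Cellular Component" list. Both an Erdos-Renyi and a preferential-
# attachment degree model are available, the latter reproducing the hub
# structure that makes degree-driven coloring informative.

#' Generator specification
#'
#' @param n_nodes number of nodes.
#' @param n_edges number of distinct undirected edges (at most
#'   `n(n-1)/2`).
#' @param comp_dist named probability vector over compartment labels
#'   (must sum to 1). The default mixes all four region kinds.
#' @param multival_cc_prob probability a node gets a multivalued
#'   "Cellular Component" list alongside its single annotation.
#' @param unknown_prob probability a node's "Selected CC" is replaced by an
#'   unrecognized or empty label (falls back to the cytosol at layout).
#' @param model `"erdos_renyi"` or `"pref_attach"`.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return A list of class `gen_spec`.
#' @export
gen_spec <- function(n_nodes, n_edges,
                     comp_dist = c(nucleus = 0.25, cytosol = 0.25,
                                   mitochondrion = 0.12,
                                   "plasma membrane" = 0.12,
                                   extracellular = 0.10,
                                   "endoplasmic reticulum" = 0.08,
                                   endosome = 0.05, "cell wall" = 0.03),
                     multival_cc_prob = 0.2, unknown_prob = 0.05,
                     model = c("erdos_renyi", "pref_attach"), seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_nodes >= 1, n_edges >= 0,
            n_edges <= n_nodes * (n_nodes - 1) / 2,
            abs(sum(comp_dist) - 1) < 1e-9,
            multival_cc_prob >= 0, multival_cc_prob <= 1,
            unknown_prob >= 0, unknown_prob <= 1)
  bad <- is.na(canonical_label(names(comp_dist)))
  if (any(bad)) stop("unknown compartment label(s) in comp_dist: ",
                     paste(names(comp_dist)[bad], collapse = ", "))
  structure(list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
                 comp_dist = comp_dist, multival_cc_prob = multival_cc_prob,
                 unknown_prob = unknown_prob, model = model,
                 seed = as.integer(seed)),
            class = "gen_spec")
}

#' Generate a synthetic annotated network
#'
#' @param spec a `gen_spec`.
#' @return A `cell_network` (same container as [parse_xgmml()] returns).
#' @export
generate_network <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_nodes
  m <- spec$n_edges
  ids <- sprintf("n%04d", seq_len(n))
  labels <- sprintf("GENE%04d", seq_len(n))

  cc <- sample(names(spec$comp_dist), n, replace = TRUE, prob = spec$comp_dist)
  unk <- stats::runif(n) < spec$unknown_prob
  if (any(unk)) {
    cc[unk] <- sample(c("", "ribosome", "proteasome"), sum(unk), replace = TRUE)
  }
  multi <- stats::runif(n) < spec$multival_cc_prob
  ccs <- vector("list", n)
  pool <- names(spec$comp_dist)
  for (i in which(multi)) {
    k <- min(sample(2:3, 1), length(pool))
    ccs[[i]] <- unique(c(canonical_label(cc[i]), sample(pool, k)))
    ccs[[i]] <- ccs[[i]][!is.na(ccs[[i]])]
  }

  if (spec$model == "erdos_renyi") {
    total <- n * (n - 1) / 2
    pick <- sort(sample(total, m))
    # unrank the unordered pair index: i is the largest with C(i,2) < pick
    i <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
    j <- pick - (i - 1) * (i - 2) / 2
    src <- ids[j]; tgt <- ids[i]
  } else {
    # preferential attachment, grown edge-by-edge to exactly m edges
    deg <- rep(1e-9, n)
    src <- character(m); tgt <- character(m)
    have <- new.env(hash = TRUE)
    k <- 0L
    active <- 2L
    deg[1:2] <- 1e-9
    while (k < m) {
      if (active < n) active <- active + 1L
      v <- active
      w <- sample(active - 1L, 1L, prob = deg[seq_len(active - 1L)] + 1)
      key <- paste(min(v, w), max(v, w))
      if (!is.null(have[[key]])) {
        # duplicate: fall back to a uniform random new pair
        v <- sample(n, 1L); w <- sample(n, 1L)
        if (v == w) next
        key <- paste(min(v, w), max(v, w))
        if (!is.null(have[[key]])) next
      }
      have[[key]] <- TRUE
      k <- k + 1L
      src[k] <- ids[min(v, w)]; tgt[k] <- ids[max(v, w)]
      deg[v] <- deg[v] + 1; deg[w] <- deg[w] + 1
    }
  }

  atts <- lapply(seq_len(n), function(i) {
    a <- list("Selected CC" = list(value = cc[i], type = "string"))
    if (length(ccs[[i]]) > 0) {
      a[["Cellular Component"]] <- list(value = ccs[[i]], type = "list")
    }
    a
  })
  nodes <- data.frame(id = ids, label = labels, selected_cc = cc,
                      x = NA_real_, y = NA_real_, visible = rep(TRUE, n),
                      fixed = rep(FALSE, n), stringsAsFactors = FALSE)
  nodes$cellular_components <- I(lapply(ccs, function(x) if (is.null(x)) character(0) else x))
  nodes$atts <- I(atts)
  edges <- data.frame(source = src, target = tgt, is_loop = src == tgt,
                      visible = rep(TRUE, length(src)), stringsAsFactors = FALSE)
  edges$atts <- I(rep(list(list()), length(src)))
  structure(list(name = sprintf("synthetic-%s-%d-%d", spec$model, n, m),
                 nodes = nodes, edges = edges),
            class = "cell_network")
}

#' Generate and serialize a synthetic network
#'
#' Writes the generated network as XGMML; identical specs produce
#' byte-identical files.
#'
#' @param spec a `gen_spec`.
#' @param path output XGMML path.
#' @return The generated `cell_network`, invisibly.
#' @export
generate_xgmml <- function(spec, path) {
  net <- generate_network(spec)
  write_xgmml(net, path)
  invisible(net)
}
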