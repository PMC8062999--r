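# Chemical reaction network structure of the mmi circuits.
#
# A network is stored as species, complexes (multisets of species, including
# the empty complex), and directed reactions between complexes. Deficiency is
# delta = n_complexes - n_linkage_classes - stoichiometric rank, with the
# rank computed in exact integer arithmetic (fraction-free Gaussian
# elimination), so the index is exact.

.complex_key <- function(cx) {
  if (length(cx) == 0L) return("0")
  cx <- cx[order(names(cx))]
  paste(ifelse(cx == 1L, names(cx), paste0(cx, "*", names(cx))), collapse = "+")
}

#' Construct a chemical reaction network
#'
#' @param species Character vector of species names.
#' @param complexes List of named integer vectors (stoichiometric multisets);
#'   the empty complex is `integer(0)`.
#' @param reactions Two-column matrix or data frame of complex indices
#'   (`from`, `to`).
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, complexes, reactions) {
  reactions <- as.matrix(reactions)
  if (ncol(reactions) != 2L) stop("reactions must have two columns")
  for (cx in complexes) {
    if (length(cx) && (!all(names(cx) %in% species) || any(cx <= 0)))
      stop("complexes must be positive multisets over the registered species")
  }
  if (any(reactions < 1L) || any(reactions > length(complexes)))
    stop("every reaction endpoint must be a registered complex")
  if (any(reactions[, 1] == reactions[, 2])) stop("self-loop reactions are not allowed")
  keys <- vapply(complexes, .complex_key, character(1))
  if (anyDuplicated(keys)) stop("duplicate complexes")
  structure(list(species = species, complexes = complexes,
                 reactions = reactions, keys = keys),
            class = "reaction_network")
}

#' Canonical reaction network of the n-site circuit
#'
#' Builds the mass-action network of the mmi-n circuit: synthesis and basal
#' decay of free mRNA and miRNA through a shared empty complex, stepwise
#' binding and unbinding, mRNA degradation inside each complex releasing the
#' bound miRNAs intact, and miRNA degradation inside each complex stepping it
#' down by one occupancy.
#'
#' @param p An [mmi_parameters] record (only `n_sites` matters).
#' @return A `reaction_network`.
#' @examples
#' net <- build_network(mmi_parameters(1))
#' deficiency(net)
#' @export
build_network <- function(p) {
  stopifnot(inherits(p, "mmi_parameters"))
  n <- p$n_sites
  sp <- c("R", "r", paste0("C", seq_len(n)))
  cx <- list(integer(0),
             c(R = 1L),
             c(r = 1L))
  add <- function(lst, v) c(lst, list(v))
  # binding-chain complexes: C_{i-1} + r and C_i
  for (i in seq_len(n)) {
    left <- if (i == 1L) c(R = 1L, r = 1L) else
      stats::setNames(c(1L, 1L), c(paste0("C", i - 1L), "r"))
    cx <- add(cx, left)
    cx <- add(cx, stats::setNames(1L, paste0("C", i)))
  }
  # mRNA-degradation product complexes i*r (i >= 2; i = 1 is the "r" complex)
  for (i in seq_len(n)) if (i >= 2L) cx <- add(cx, c(r = as.integer(i)))
  keys <- vapply(cx, .complex_key, character(1))
  dup <- !duplicated(keys)
  cx <- cx[dup]; keys <- keys[dup]
  idx <- function(v) match(.complex_key(v), keys)
  rx <- rbind(
    c(idx(integer(0)), idx(c(R = 1L))),   # synthesis R
    c(idx(c(R = 1L)), idx(integer(0))),   # decay R
    c(idx(integer(0)), idx(c(r = 1L))),   # synthesis r
    c(idx(c(r = 1L)), idx(integer(0))))   # decay r
  for (i in seq_len(n)) {
    left <- if (i == 1L) c(R = 1L, r = 1L) else
      stats::setNames(c(1L, 1L), c(paste0("C", i - 1L), "r"))
    ci <- stats::setNames(1L, paste0("C", i))
    rx <- rbind(rx, c(idx(left), idx(ci)), c(idx(ci), idx(left)))
  }
  for (i in seq_len(n)) {
    ci <- stats::setNames(1L, paste0("C", i))
    rx <- rbind(rx, c(idx(ci), idx(c(r = as.integer(i)))))      # mRNA degraded
    down <- if (i == 1L) c(R = 1L) else stats::setNames(1L, paste0("C", i - 1L))
    rx <- rbind(rx, c(idx(ci), idx(down)))                      # miRNA degraded
  }
  colnames(rx) <- c("from", "to")
  reaction_network(sp, cx, rx)
}

# exact integer rank via fraction-free (Bareiss) elimination
.integer_rank <- function(M) {
  M <- matrix(as.numeric(M), nrow = nrow(M))
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  r <- 0L
  prev <- 1
  for (col in seq_len(ncol(M))) {
    piv <- which(abs(M[(r + 1L):nrow(M), col]) > 0)
    if (length(piv) == 0L) next
    piv <- piv[1] + r
    if (piv != r + 1L) M[c(r + 1L, piv), ] <- M[c(piv, r + 1L), ]
    r <- r + 1L
    if (r == nrow(M)) break
    below <- (r + 1L):nrow(M)
    M[below, ] <- (M[r, col] * M[below, , drop = FALSE] -
                     outer(M[below, col], M[r, ])) / prev
    prev <- M[r, col]
  }
  # count nonzero rows actually used as pivots
  r
}

# stoichiometric matrix: species x reactions, integer entries
.stoich_matrix <- function(net) {
  sp <- net$species
  S <- matrix(0L, nrow = length(sp), ncol = nrow(net$reactions),
              dimnames = list(sp, NULL))
  vecof <- function(cx) {
    v <- stats::setNames(integer(length(sp)), sp)
    if (length(cx)) v[names(cx)] <- cx
    v
  }
  for (k in seq_len(nrow(net$reactions))) {
    S[, k] <- vecof(net$complexes[[net$reactions[k, 2]]]) -
      vecof(net$complexes[[net$reactions[k, 1]]])
  }
  S
}

#' Deficiency and structural indices of a reaction network
#'
#' Computes `delta = n_complexes - n_linkage_classes - stoichiometric rank`,
#' with linkage classes as connected components of the undirected complex
#' graph and the rank computed exactly over the integers.
#'
#' @param net A `reaction_network`.
#' @return A list of class `crnt_report`: `n_complexes`,
#'   `n_linkage_classes`, `stoich_rank`, `deficiency`, `weakly_reversible`.
#' @export
deficiency <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  g <- igraph::graph_from_edgelist(net$reactions, directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, length(net$complexes) -
                                     igraph::vcount(g)))
  ncx <- length(net$complexes)
  l <- as.integer(igraph::count_components(g, mode = "weak"))
  s <- as.integer(.integer_rank(.stoich_matrix(net)))
  structure(list(n_complexes = ncx, n_linkage_classes = l, stoich_rank = s,
                 deficiency = ncx - l - s,
                 weakly_reversible = weak_reversibility(net)),
            class = "crnt_report")
}

#' @export
print.crnt_report <- function(x, ...) {
  cat(sprintf("complexes n = %d, linkage classes l = %d, rank s = %d -> deficiency = %d\n",
              x$n_complexes, x$n_linkage_classes, x$stoich_rank, x$deficiency))
  cat(sprintf("weakly reversible: %s\n", x$weakly_reversible))
  if (x$deficiency == 0L) {
    cat("deficiency zero theorem applies: no positive multistationarity",
        "for any mass-action rate constants\n")
  } else if (x$deficiency == 1L) {
    cat("deficiency one theory applies (subject to its linkage-class",
        "conditions); multistationarity is not excluded structurally\n")
  } else {
    cat("deficiency > 1: the deficiency theorems give no structural verdict\n")
  }
  invisible(x)
}

#' Weak reversibility of a reaction network
#'
#' A network is weakly reversible iff every reaction lies on a directed cycle
#' of the complex graph, i.e. both endpoints of every reaction fall in the
#' same strongly connected component.
#'
#' @param net A `reaction_network`.
#' @return Logical.
#' @export
weak_reversibility <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  g <- igraph::graph_from_edgelist(net$reactions, directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, length(net$complexes) -
                                     igraph::vcount(g)))
  comp <- igraph::components(g, mode = "strong")$membership
  all(comp[net$reactions[, 1]] == comp[net$reactions[, 2]])
}
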