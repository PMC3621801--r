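#' Labelled network
#'
#' Construct an undirected labelled network from a square weight matrix.
#' A zero entry means "no edge"; any nonzero entry is both the edge
#' indicator and the edge weight (e.g. a thresholded correlation).
#' Loops are not allowed: the diagonal is ignored and stored as zero.
#'
#' @param W square numeric matrix of edge weights. Must be symmetric up to
#'   `tol`; the stored matrix is the exact average of `W` and `t(W)`.
#' @param labels character vector of unique node labels. Defaults to the
#'   rownames of `W`, or `"v1".."vn"` when `W` carries none.
#' @param tol tolerance for the symmetry check.
#' @return An object of class `"labeled_network"`: a list with elements
#'   `W` (weight matrix with labelled dimnames and zero diagonal) and
#'   `labels`.
#' @examples
#' W <- matrix(0, 3, 3)
#' W[1, 2] <- W[2, 1] <- 1
#' net <- labeled_network(W, labels = c("a", "b", "c"))
#' net
#' @seealso [align_networks()], [net_dissim()]
#' @export
labeled_network <- function(W, labels = NULL, tol = 1e-10) {
  W <- as.matrix(W)
  if (!is.numeric(W)) stop("'W' must be a numeric matrix", call. = FALSE)
  if (nrow(W) != ncol(W)) stop("'W' must be square", call. = FALSE)
  if (anyNA(W) || any(!is.finite(W))) {
    stop("'W' must be finite and free of missing values", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(W)
    if (is.null(labels)) labels <- paste0("v", seq_len(nrow(W)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(W)) {
    stop("number of labels must equal the matrix dimension", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("node labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (max(abs(W - t(W))) > tol) {
    stop("'W' is not symmetric (undirected networks only); ",
         "use read_network(symmetrize = TRUE) for asymmetric input",
         call. = FALSE)
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- list(labels, labels)
  structure(list(W = W, labels = labels), class = "labeled_network")
}

#' Coerce to a labelled network
#'
#' @param x a `labeled_network` or a square numeric matrix.
#' @param ... passed to [labeled_network()].
#' @return A `labeled_network`.
#' @export
as_labeled_network <- function(x, ...) {
  if (inherits(x, "labeled_network")) return(x)
  labeled_network(x, ...)
}

#' @export
as.matrix.labeled_network <- function(x, ...) x$W

#' @export
labels.labeled_network <- function(object, ...) object$labels

#' Number of nodes of a network
#' @param net a `labeled_network`.
#' @return Integer node count.
#' @export
network_order <- function(net) length(as_labeled_network(net)$labels)

#' Number of edges of a network
#' @param net a `labeled_network`.
#' @param zero_tol entries with absolute value at or below this are
#'   treated as absent edges.
#' @return Integer edge count (each unordered pair counted once).
#' @export
network_size <- function(net, zero_tol = 0) {
  W <- as_labeled_network(net)$W
  sum(abs(W[upper.tri(W)]) > zero_tol)
}

#' @export
print.labeled_network <- function(x, ...) {
  cat(sprintf("Labelled undirected network: %d nodes, %d edges\n",
              network_order(x), network_size(x)))
  cat("Nodes:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Align two labelled networks
#'
#' Reorders both networks to a common (lexicographic) label order so that
#' row/column i refers to the same node in both. Weights are unchanged.
#'
#' @param a,b `labeled_network` objects (or square matrices) over the same
#'   label set.
#' @return A list with elements `a` and `b`, both reordered.
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
#' V <- W[c("y", "x"), c("y", "x")]
#' al <- align_networks(labeled_network(W), labeled_network(V))
#' identical(al$a$labels, al$b$labels)
#' @export
align_networks <- function(a, b) {
  a <- as_labeled_network(a)
  b <- as_labeled_network(b)
  la <- a$labels
  lb <- b$labels
  if (!setequal(la, lb)) {
    extra <- sort(c(setdiff(la, lb), setdiff(lb, la)))
    stop("cannot align networks: label sets differ by {",
         paste(extra, collapse = ", "), "}", call. = FALSE)
  }
  ord <- sort(la)
  list(a = labeled_network(a$W[ord, ord, drop = FALSE], labels = ord),
       b = labeled_network(b$W[ord, ord, drop = FALSE], labels = ord))
}

# Align only when needed; returns list of weight matrices in matching order.
.aligned_pair <- function(observed, target) {
  observed <- as_labeled_network(observed)
  target <- as_labeled_network(target)
  if (identical(observed$labels, target$labels)) {
    return(list(WO = observed$W, WT = target$W, labels = observed$labels))
  }
  al <- align_networks(observed, target)
  list(WO = al$a$W, WT = al$b$W, labels = al$a$labels)
}
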