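#' Read a labelled network from a TSV file
#'
#' Two plain-text formats are supported. `"adjacency"`: a tab-separated
#' square matrix with a header row and a first column of node labels; a
#' cell holds the edge weight and `0` means no edge. `"edgelist"`: three
#' tab-separated columns `node_a`, `node_b`, `weight` (header required);
#' isolated nodes are supplied through `labels`.
#'
#' @param path file path.
#' @param format `"adjacency"` or `"edgelist"`.
#' @param labels optional complete node-label vector (edge lists only);
#'   labels absent from the edge list become isolated nodes.
#' @param symmetrize adjacency matrices that are not symmetric are
#'   rejected unless this is `TRUE`, in which case each dyad keeps the
#'   entry of larger magnitude.
#' @return A `labeled_network`.
#' @export
read_network <- function(path, format = c("adjacency", "edgelist"),
                         labels = NULL, symmetrize = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "adjacency") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, row.names = 1L,
                             colClasses = "character")
    labs <- rownames(tab)
    if (!identical(colnames(tab), labs)) {
      stop("adjacency header labels do not match the label column",
           call. = FALSE)
    }
    if (anyDuplicated(labs)) {
      stop("duplicate node labels in ", path, call. = FALSE)
    }
    W <- suppressWarnings(
      matrix(as.numeric(as.matrix(tab)), nrow(tab), ncol(tab)))
    if (anyNA(W)) stop("non-numeric cell(s) in ", path, call. = FALSE)
    if (symmetrize) {
      keep_upper <- abs(W) >= abs(t(W))
      W <- ifelse(keep_upper, W, t(W))
    }
    return(labeled_network(W, labels = labs))
  }
  el <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(el) < 3L) {
    stop("edge list needs columns node_a, node_b, weight", call. = FALSE)
  }
  names(el)[1:3] <- c("node_a", "node_b", "weight")
  if (!is.numeric(el$weight)) {
    stop("non-numeric weights in ", path, call. = FALSE)
  }
  labs <- unique(c(el$node_a, el$node_b, labels))
  W <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  seen <- matrix(FALSE, length(labs), length(labs),
                 dimnames = list(labs, labs))
  for (k in seq_len(nrow(el))) {
    a <- el$node_a[k]; b <- el$node_b[k]; w <- el$weight[k]
    if (a == b) stop("loop edge on node ", a, " is not allowed",
                     call. = FALSE)
    if (seen[a, b] && W[a, b] != w) {
      stop("conflicting entries for edge ", a, "--", b, call. = FALSE)
    }
    W[a, b] <- W[b, a] <- w
    seen[a, b] <- seen[b, a] <- TRUE
  }
  labeled_network(W, labels = labs)
}

#' Write a labelled network to a TSV file
#'
#' Writes at full double precision so that a read/write round trip is
#' exact.
#'
#' @param net a `labeled_network`.
#' @param path output path.
#' @param format `"adjacency"` or `"edgelist"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("adjacency", "edgelist")) {
  format <- match.arg(format)
  net <- as_labeled_network(net)
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  if (format == "adjacency") {
    W <- net$W
    lines <- c(paste(c("", net$labels), collapse = "\t"),
               vapply(seq_len(nrow(W)), function(i) {
                 paste(c(net$labels[i], fmt(W[i, ])), collapse = "\t")
               }, character(1)))
    writeLines(lines, path)
  } else {
    W <- net$W
    idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    lines <- c("node_a\tnode_b\tweight",
               apply(idx, 1L, function(ij) {
                 paste(net$labels[ij[1]], net$labels[ij[2]],
                       fmt(W[ij[1], ij[2]]), sep = "\t")
               }))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a samples-by-variables data matrix
#'
#' Accepts a rectangular numeric CSV or TSV (by file extension; `.tsv`
#' and `.txt` are read as tab-separated) with a header of variable
#' labels. Missing values are rejected. A matrix with more columns than
#' rows is accepted with a warning, since expression data is often
#' shipped transposed.
#'
#' @param path file path.
#' @return A numeric matrix with column names.
#' @export
read_data_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE)
  X <- as.matrix(df)
  if (!is.numeric(X)) {
    stop("non-numeric column(s) in ", path, call. = FALSE)
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column '%s'", bad[1L],
                 colnames(X)[bad[2L]]), call. = FALSE)
  }
  if (ncol(X) > nrow(X)) {
    warning("more variables than samples; check the matrix orientation ",
            "(rows must be samples)", call. = FALSE)
  }
  X
}

#' Serialize a test result to JSON
#'
#' @param x a `netdiss_test`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @param full_null include the complete null vector (otherwise a
#'   five-number summary).
#' @return The JSON string, invisibly when written to a file.
#' @export
test_result_json <- function(x, path = NULL, full_null = FALSE) {
  stopifnot(inherits(x, "netdiss_test"))
  qs <- stats::quantile(x$null, c(0, .25, .5, .75, 1))
  obj <- list(d_observed = x$statistic, p_value = x$p.value, B = x$B,
              seed = x$seed,
              null_summary = list(min = qs[[1]], q25 = qs[[2]],
                                  median = qs[[3]], q75 = qs[[4]],
                                  max = qs[[5]]))
  if (full_null) obj$null <- x$null
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
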