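#' Electrode montages and adjacency graphs
#'
#' A montage holds ordered electrode labels and unit-sphere 3D positions.
#' The adjacency graph built from a montage (electrodes closer than a chord
#' distance threshold are neighbours) defines which electrodes may join the
#' same cluster in [cluster_permutation_test()].
#'
#' @param path Path to a text file with one row per electrode: label, x, y, z.
#'   Whitespace- or comma-separated; an optional header row is detected and
#'   skipped.
#' @param reference_note Free-text description of the recording reference.
#' @return `load_montage()` returns a `montage` object: a list with `labels`
#'   (character), `positions` (n x 3 matrix of unit vectors) and
#'   `reference_note`.
#' @examples
#' mon <- biosemi64_montage()
#' adj <- build_adjacency(mon)
#' @export
load_montage <- function(path, reference_note = "") {
  if (!file.exists(path)) stop("montage file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(raw) < 4) stop("montage file needs 4 columns: label, x, y, z")
  # header row: any non-numeric coordinate field in row 1
  coords1 <- suppressWarnings(as.numeric(unlist(raw[1, 2:4])))
  if (anyNA(coords1)) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) stop("montage file has no electrode rows")
  labels <- as.character(raw[[1]])
  if (anyDuplicated(labels))
    stop("duplicate electrode label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  pos <- suppressWarnings(matrix(as.numeric(as.matrix(raw[, 2:4])),
                                 ncol = 3))
  if (anyNA(pos) || any(!is.finite(pos)))
    stop("non-numeric or non-finite coordinate in montage file")
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm == 0)) stop("zero-length electrode position")
  pos <- pos / nrm
  dimnames(pos) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, positions = pos,
                 reference_note = reference_note),
            class = "montage")
}

#' @describeIn load_montage The packaged idealized 64-channel Biosemi 10-10
#'   montage (unit-sphere positions derived from the standard 10-10 angular
#'   layout; not digitized head coordinates).
#' @export
biosemi64_montage <- function() {
  load_montage(system.file("extdata", "biosemi64_sphere.tsv",
                           package = "eegsync"),
               reference_note = "idealized 10-10 sphere, average reference")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$labels), " electrodes: ",
      paste(utils::head(x$labels, 4), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' @rdname load_montage
#' @param montage A `montage` object.
#' @param threshold Chord-distance threshold (dimensionless, on the unit
#'   sphere).  The default 0.5 yields a median node degree of about 8 on the
#'   packaged 64-channel montage.
#' @return `build_adjacency()` returns an `adjacency` object: `n_nodes`,
#'   `labels`, and `edges`, a two-column matrix of node index pairs (i < j).
#' @export
build_adjacency <- function(montage, threshold = 0.5) {
  stopifnot(inherits(montage, "montage"))
  n <- length(montage$labels)
  if (n < 2) stop("need at least 2 electrodes")
  if (threshold <= 0) stop("threshold must be > 0")
  D <- as.matrix(stats::dist(montage$positions))
  idx <- which(upper.tri(D) & D < threshold, arr.ind = TRUE)
  edges <- unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE])
  adj <- structure(list(n_nodes = n, labels = montage$labels, edges = edges),
                   class = "adjacency")
  comp <- graph_components(neighbor_list(adj), seq_len(n))
  if (max(comp) > 1L)
    warning("adjacency graph is disconnected (", max(comp),
            " components); clusters cannot span components")
  adj
}

#' @export
print.adjacency <- function(x, ...) {
  cat("<adjacency> ", x$n_nodes, " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

# neighbor index list from an adjacency object
neighbor_list <- function(adj) {
  nb <- vector("list", adj$n_nodes)
  for (k in seq_len(nrow(adj$edges))) {
    i <- adj$edges[k, 1]; j <- adj$edges[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# Connected-component labels restricted to `nodes` (integer vector).
# Returns an integer vector parallel to `nodes`; labels start at 1.
# Implemented as plain BFS: it sits in the permutation-null inner loop of the
# cluster test, where the active node set is typically tiny.
graph_components <- function(nb, nodes) {
  if (length(nodes) == 0) return(integer(0))
  n <- length(nb)
  comp_full <- integer(n)
  in_set <- logical(n)
  in_set[nodes] <- TRUE
  lab <- 0L
  for (s in nodes) {
    if (comp_full[s] > 0L) next
    lab <- lab + 1L
    frontier <- s
    comp_full[s] <- lab
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nb[[v]]) {
          if (in_set[w] && comp_full[w] == 0L) {
            comp_full[w] <- lab
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
  }
  comp_full[nodes]
}
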