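#' Default-mode-network specification
#'
#' A `dmn_spec` describes the modelled network: named nodes with MNI
#' coordinates, the list of typed directed edges (the A-matrix structure), and
#' named edge subsets used by the cross-validation analyses.
#'
#' @param nodes data.frame with columns `name` and `x`, `y`, `z` (mm).
#' @param edges data.frame with columns `source`, `target` (node names) and
#'   `type` (one of `"forward"`, `"backward"`, `"lateral"`).
#' @param subsets named list mapping subset labels to integer edge indices.
#' @return An object of class `dmn_spec`.
#' @export
dmn_spec <- function(nodes, edges, subsets = list()) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  spec <- structure(list(nodes = nodes, edges = edges, subsets = subsets),
                    class = "dmn_spec")
  validate_dmn_spec(spec)
  spec
}

validate_dmn_spec <- function(spec) {
  nodes <- spec$nodes; edges <- spec$edges
  if (nrow(nodes) != 4L) stop("network must have exactly 4 nodes")
  if (anyDuplicated(nodes$name)) stop("node names must be unique")
  if (nrow(edges) != 12L) stop("network must have exactly 12 directed edges")
  if (!all(edges$source %in% nodes$name) || !all(edges$target %in% nodes$name))
    stop("edges reference unknown nodes")
  if (any(edges$source == edges$target)) stop("self-edges are not allowed")
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key)) stop("each ordered node pair must appear exactly once")
  if (!all(edges$type %in% c("forward", "backward", "lateral")))
    stop("edge types must be forward, backward or lateral")
  for (nm in names(spec$subsets)) {
    idx <- spec$subsets[[nm]]
    if (!all(idx %in% seq_len(12L))) stop("subset '", nm, "' references invalid edge indices")
  }
  invisible(spec)
}

#' The four-node default mode network
#'
#' Returns the modelled DMN: medial prefrontal cortex (mPFC), posterior
#' cingulate/precuneus (Prec) and bilateral lateral parietal cortices
#' (lLP, rLP), fully connected by 12 directed edges. Edge types follow the
#' hierarchy mPFC > Prec > lLP, rLP: connections ascending the hierarchy are
#' forward (driving, targeting the granular layer), descending ones are
#' backward (modulatory/inhibitory), and the two interparietal connections are
#' lateral. Named subsets: `full` (all 12), `frontoparietal` (the 6 edges
#' incident to mPFC) and `parietal` (the 6 edges among lLP, rLP, Prec).
#'
#' @return A `dmn_spec`.
#' @examples
#' net <- default_dmn()
#' net$edges
#' @export
default_dmn <- function() {
  nodes <- data.frame(
    name = c("lLP", "rLP", "Prec", "mPFC"),
    x = c(-46, 49, 0, -1),
    y = c(-66, -63, -52, 54),
    z = c(30, 33, 7, 27)
  )
  edges <- data.frame(
    source = c("lLP", "rLP", "Prec", "lLP", "rLP",
               "mPFC", "mPFC", "mPFC", "Prec", "Prec",
               "lLP", "rLP"),
    target = c("mPFC", "mPFC", "mPFC", "Prec", "Prec",
               "lLP", "rLP", "Prec", "lLP", "rLP",
               "rLP", "lLP"),
    type = c(rep("forward", 5), rep("backward", 5), rep("lateral", 2))
  )
  mpfc <- which(edges$source == "mPFC" | edges$target == "mPFC")
  post <- which(edges$source != "mPFC" & edges$target != "mPFC")
  dmn_spec(nodes, edges,
           subsets = list(full = 1:12, frontoparietal = mpfc, parietal = post))
}

#' @export
print.dmn_spec <- function(x, ...) {
  cat("dmn_spec:", nrow(x$nodes), "nodes,", nrow(x$edges), "directed edges\n")
  cat("nodes:", paste(x$nodes$name, collapse = ", "), "\n")
  cat("subsets:", paste(names(x$subsets), collapse = ", "), "\n")
  invisible(x)
}

# index of an edge by source/target name
edge_index <- function(spec, source, target) {
  i <- which(spec$edges$source == source & spec$edges$target == target)
  if (!length(i)) stop("no edge ", source, "->", target)
  i
}

# human-readable edge labels in canonical order
edge_labels <- function(spec) paste0(spec$edges$source, "->", spec$edges$target)
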