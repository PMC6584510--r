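#' Motif patterns
#'
#' A `pomoc_motif` is a small weakly connected directed graph whose
#' occurrences (embeddings) are counted in a larger network. Four named
#' patterns conserved across biological networks are built in:
#'
#' * `bifan`: two regulators jointly targeting two genes
#'   (`a->c, a->d, b->c, b->d`);
#' * `biparallel`: two parallel two-step paths from one source to one sink
#'   (`a->b, a->c, b->d, c->d`);
#' * `cascade`: a two-step regulatory chain (`a->b, b->c`);
#' * `feed_forward`: the feed-forward loop (`a->b, b->c, a->c`).
#'
#' @param pattern either the name of a builtin (`"bifan"`, `"biparallel"`,
#'   `"cascade"`, `"feed_forward"`) or a two-column data frame / matrix of
#'   directed motif edges for a custom pattern.
#' @param name label stored with a custom pattern (default `"custom"`).
#' @return object of class `pomoc_motif` with elements `name`, `edges`
#'   (character `source`/`target` data frame) and `nodes`.
#' @examples
#' motif_pattern("feed_forward")
#' motif_pattern(data.frame(from = c("a", "a", "b"), to = c("b", "c", "d")))
#' @export
motif_pattern <- function(pattern, name = "custom") {
  builtins <- list(
    bifan        = data.frame(source = c("a", "a", "b", "b"),
                              target = c("c", "d", "c", "d")),
    biparallel   = data.frame(source = c("a", "a", "b", "c"),
                              target = c("b", "c", "d", "d")),
    cascade      = data.frame(source = c("a", "b"), target = c("b", "c")),
    feed_forward = data.frame(source = c("a", "b", "a"),
                              target = c("b", "c", "c"))
  )
  if (is.character(pattern) && length(pattern) == 1L) {
    if (!pattern %in% names(builtins)) {
      stop("unknown motif '", pattern, "'; builtins are: ",
           paste(names(builtins), collapse = ", "))
    }
    edges <- builtins[[pattern]]
    name <- pattern
  } else {
    edges <- as.data.frame(pattern, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) stop("a custom motif needs source and target columns")
    edges <- data.frame(source = as.character(edges[[1L]]),
                        target = as.character(edges[[2L]]))
  }
  nodes <- unique(c(rbind(edges$source, edges$target)))
  motif <- structure(list(name = name, edges = edges, nodes = nodes),
                     class = "pomoc_motif")
  check_motif(motif)
  motif
}

check_motif <- function(motif) {
  e <- motif$edges
  if (any(e$source == e$target)) stop("motif patterns may not contain self-loops")
  if (anyDuplicated(paste(e$source, e$target, sep = "\r"))) {
    stop("motif patterns may not contain duplicated edges")
  }
  if (nrow(e) < 2L) stop("a motif needs at least two edges")
  # weak connectivity
  g <- igraph::graph_from_data_frame(e, directed = TRUE)
  if (!igraph::is_connected(g, mode = "weak")) stop("motif must be weakly connected")
  invisible(motif)
}

#' @export
print.pomoc_motif <- function(x, ...) {
  cat(sprintf("Motif '%s': %d nodes, %d edges\n", x$name,
              length(x$nodes), nrow(x$edges)))
  cat(paste(sprintf("  %s -> %s", x$edges$source, x$edges$target),
            collapse = "\n"), "\n")
  invisible(x)
}

as_igraph_motif <- function(motif) {
  igraph::graph_from_data_frame(motif$edges, directed = TRUE)
}
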