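#' Read a directed network from a file
#'
#' Edge-list TSV format: `source<TAB>target[<TAB>capacity]`, one edge per
#' line, `#` comment lines and blank lines ignored; the file order defines
#' the edge indices. A missing capacity column is filled with
#' `default_capacity` (`Inf`, the unconstrained F1 regime, by default).
#' GraphML files are read through igraph; a `capacity` edge attribute is
#' honored when present.
#'
#' @param path file to read.
#' @param default_capacity capacity for edges without an explicit one.
#' @param format `"auto"` (by extension), `"tsv"` or `"graphml"`.
#' @param drop_self_loops self-loops are an error by default (`FALSE`);
#'   `TRUE` downgrades to dropping them with a warning.
#' @return a [pomoc_network()].
#' @export
read_network <- function(path, default_capacity = Inf,
                         format = c("auto", "tsv", "graphml"),
                         drop_self_loops = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!igraph::is_directed(g)) stop("GraphML network must be directed")
    el <- igraph::as_edgelist(g, names = TRUE)
    cap <- igraph::edge_attr(g, "capacity")
    if (is.null(cap)) cap <- rep(default_capacity, nrow(el))
    df <- data.frame(source = as.character(el[, 1L]),
                     target = as.character(el[, 2L]), capacity = as.numeric(cap))
  } else {
    lines <- readLines(path)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (!length(keep)) stop("no edges in ", path)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(parts)
    first <- parts[[1L]]
    header <- identical(tolower(first[1:2]), c("source", "target"))
    if (header) { parts <- parts[-1L]; nf <- nf[-1L]; keep <- keep[-1L] }
    if (any(nf < 2L)) {
      stop("malformed line ", keep[which(nf < 2L)[1L]], " in ", path,
           ": need at least source<TAB>target")
    }
    src <- vapply(parts, `[`, "", 1L)
    tgt <- vapply(parts, `[`, "", 2L)
    cap <- vapply(parts, function(x) {
      if (length(x) < 3L || !nzchar(x[3L])) return(NA_real_)
      suppressWarnings(as.numeric(x[3L]))
    }, 0)
    badcap <- which(lengths(parts) >= 3L & is.na(cap))
    if (length(badcap)) {
      stop("malformed capacity on line ", keep[badcap[1L]], " in ", path)
    }
    lt1 <- which(!is.na(cap) & cap < 1)
    if (length(lt1)) {
      stop("capacity < 1 on line ", keep[lt1[1L]], " in ", path)
    }
    cap[is.na(cap)] <- default_capacity
    df <- data.frame(source = src, target = tgt, capacity = cap)
  }
  loops <- which(df$source == df$target)
  if (length(loops)) {
    if (drop_self_loops) {
      warning("dropping ", length(loops), " self-loop(s)")
      df <- df[-loops, , drop = FALSE]
    } else {
      stop("self-loop at edge ", loops[1L], " (", df$source[loops[1L]],
           " -> ", df$target[loops[1L]], "); no motif contains one. ",
           "Use drop_self_loops = TRUE to drop with a warning.")
    }
  }
  pomoc_network(df[, c("source", "target")], capacity = df$capacity)
}

#' Write a network as edge-list TSV
#'
#' Inverse of [read_network()]: writes `source<TAB>target<TAB>capacity` with
#' a header line, preserving edge order; unbounded capacities are written as
#' `Inf`.
#'
#' @param network a [pomoc_network()].
#' @param path output file.
#' @export
write_network <- function(network, path) {
  df <- data.frame(source = network$edges$source,
                   target = network$edges$target,
                   capacity = network$capacity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif pattern from a name or file
#'
#' @param spec a builtin motif name (see [motif_pattern()]) or the path of a
#'   two-column edge-list TSV describing a custom pattern.
#' @return a [motif_pattern()].
#' @export
read_motif <- function(spec) {
  builtin <- c("bifan", "biparallel", "cascade", "feed_forward")
  if (spec %in% builtin) return(motif_pattern(spec))
  if (!file.exists(spec)) {
    stop("'", spec, "' is neither a builtin motif (",
         paste(builtin, collapse = ", "), ") nor a readable file")
  }
  net <- read_network(spec, default_capacity = Inf, format = "tsv")
  motif_pattern(net$edges, name = sub("\\.[^.]*$", "", basename(spec)))
}

#' Read an expression profile
#'
#' TSV with `gene<TAB>value` rows (optional header, `#` comments ignored).
#'
#' @param path file to read.
#' @return named numeric vector of expression values.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(parts) && identical(tolower(parts[[1L]][1L]), "gene")) {
    parts <- parts[-1L]; keep <- keep[-1L]
  }
  if (any(lengths(parts) < 2L)) {
    stop("malformed line ", keep[which(lengths(parts) < 2L)[1L]], " in ", path)
  }
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(val)) {
    stop("non-numeric expression value on line ", keep[which(is.na(val))[1L]],
         " in ", path)
  }
  stats::setNames(val, vapply(parts, `[`, "", 1L))
}

#' Serialize a solution to JSON or TSV
#'
#' JSON output round-trips the count, measure, seed, solver settings, the
#' 1-based edge-index list of every selected embedding, the per-edge usage
#' vector and the per-gene motif counts. TSV output has one row per
#' embedding with its comma-joined edge indices.
#'
#' @param solution a `pomoc_solution`.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @export
write_solution <- function(solution, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      count = solution$size,
      measure = solution$measure,
      motif = solution$motif$name,
      seed = solution$seed,
      config = list(p = solution$control$p,
                    stall_limit = solution$control$stall_limit),
      iterations = solution$iterations,
      f1 = solution$f1,
      guaranteed = solution$guaranteed,
      embeddings = lapply(solution$embeddings, as.integer),
      usage = as.integer(solution$usage),
      capacity = ifelse(is.infinite(solution$capacity), "Inf",
                        as.character(solution$capacity)),
      per_gene_counts = as.list(per_gene_motif_counts(solution,
                                                      solution$network))
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- data.frame(
      embedding = seq_along(solution$embeddings),
      edges = vapply(solution$embeddings, paste, "", collapse = ","))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
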