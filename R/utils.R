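# Shared internal helpers: error conditions, edge keys, plain graph algorithms.

stop_supercut <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "supercut_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

domain_error   <- function(msg, ...) stop_supercut(msg, "supercut_domain_error", ...)
parse_error    <- function(msg, offset = NA_integer_) {
  stop_supercut(sprintf("%s (at offset %d)", msg, offset), "supercut_parse_error",
                offset = offset)
}
resource_error <- function(msg, ...) stop_supercut(msg, "supercut_resource_error", ...)
fixture_error  <- function(msg) stop_supercut(msg, "supercut_fixture_error")
internal_error <- function(msg) stop_supercut(msg, "supercut_internal_error")

EDGE_SEP <- "--"

#' @noRd
edge_key <- function(u, v) {
  a <- pmin(u, v); b <- pmax(u, v)
  paste(a, b, sep = EDGE_SEP)
}

# m x 2 character matrix -> canonical keys
edge_keys <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(character(0))
  edge_key(edges[, 1L], edges[, 2L])
}

keys_to_edges <- function(keys) {
  if (length(keys) == 0L) return(matrix(character(0), 0L, 2L))
  parts <- strsplit(keys, EDGE_SEP, fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) domain_error(sprintf("malformed edge key: %s", keys[bad][1L]))
  matrix(unlist(parts), ncol = 2L, byrow = TRUE)
}

# Normalise an edge-set argument (keys or 2-column matrix) to sorted keys.
as_edge_keys <- function(f) {
  if (is.matrix(f)) f <- edge_keys(f)
  sort(unique(as.character(f)))
}

# Row-level canonical form and keys for edge matrices whose vertex ids may
# themselves contain the display edge separator (e.g. ELIG-level edges).
# "\r" cannot occur in a vertex id, so these keys are always unambiguous.
canon_rows <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
}

row_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  e <- canon_rows(edges)
  paste(e[, 1L], e[, 2L], sep = "\r")
}

dedupe_edges <- function(edges) {
  e <- canon_rows(edges)
  k <- row_keys(e)
  e <- e[!duplicated(k), , drop = FALSE]
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

# Adjacency list keyed by vertex id.
adjacency_list <- function(vertices, edges) {
  adj <- vector("list", length(vertices))
  names(adj) <- vertices
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1L]; v <- edges[i, 2L]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
  }
  adj
}

# Connected-component membership (integer, named by vertex) of a plain graph.
graph_components <- function(vertices, edges) {
  n <- length(vertices)
  comp <- integer(n); names(comp) <- vertices
  if (n == 0L) return(comp)
  adj <- adjacency_list(vertices, edges)
  cid <- 0L
  for (s in vertices) {
    if (comp[[s]] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[[s]] <- cid
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp[[w]] == 0L) { comp[[w]] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

graph_is_connected <- function(vertices, edges) {
  length(vertices) <= 1L || max(graph_components(vertices, edges)) == 1L
}

# Remove a set of edges (by key) from an edge matrix.
drop_edges <- function(edges, keys) {
  if (nrow(edges) == 0L) return(edges)
  edges[!(edge_keys(edges) %in% keys), , drop = FALSE]
}

# Suppress degree-2 vertices that are not in `protect`; used after pruning.
suppress_degree2 <- function(vertices, edges, protect = character(0)) {
  repeat {
    if (nrow(edges) == 0L) break
    deg <- table(factor(c(edges[, 1L], edges[, 2L]), levels = vertices))
    sup <- vertices[deg == 2L & !(vertices %in% protect)]
    if (length(sup) == 0L) break
    v <- sup[[1L]]
    inc <- which(edges[, 1L] == v | edges[, 2L] == v)
    nb <- setdiff(as.vector(edges[inc, , drop = FALSE]), v)
    edges <- edges[-inc, , drop = FALSE]
    edges <- rbind(edges, matrix(nb, 1L, 2L))
    vertices <- setdiff(vertices, v)
  }
  list(vertices = vertices, edges = edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
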