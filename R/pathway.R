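#' Construct a signed topological pathway
#'
#' A pathway is a signed directed graph of typed nodes (ligand, receptor,
#' kinase, tf, target, process) together with a set of *routes*: ordered
#' chains of genes ending at the designated transcription factor (TF). Each
#' gene on a route carries a net sign to the TF, the product of the edge
#' signs along the route segment from that gene to the TF. Routes are
#' curation units and may be declared explicitly; for acyclic pathways they
#' can be enumerated automatically with [enumerate_routes()].
#'
#' @param nodes Data frame with columns `id` (HGNC-style gene symbol, or a
#'   label for the biological-process node) and `role` (one of `"ligand"`,
#'   `"receptor"`, `"kinase"`, `"tf"`, `"target"`, `"process"`). Exactly one
#'   node must have role `"process"` and at least one must have role `"tf"`.
#' @param edges Data frame with columns `src`, `dst` and `sign`
#'   (+1 activation, -1 inhibition). Endpoints must be declared nodes; no
#'   self-loops; each (src, dst) pair at most once.
#' @param routes Optional data frame with columns `route_id` and `genes`
#'   (a list column of character vectors), or a named list of character
#'   vectors. Each route must end at the TF. When `NULL`, routes are left
#'   empty and can be filled by [enumerate_routes()].
#' @param name Pathway name.
#' @param tf Identifier of the TF the routes converge on. Defaults to the
#'   single node with role `"tf"` (must be given explicitly if several).
#' @param up_targets,down_targets Optional character vectors of Up / Down
#'   target genes (normally set via [extend_pathway()]).
#'
#' @return An object of class `pd_pathway`: a list with tidy `nodes`,
#'   `edges` and `routes` tibbles (routes in long form: `route_id`,
#'   `position`, `gene`, `net_sign`), the `tf`, the `process` node id and
#'   the target sets.
#' @export
#' @examples
#' p <- pathway(
#'   nodes = data.frame(
#'     id   = c("IFNG", "IFNGR1", "JAK1", "STAT1", "TBX21", "Th1_diff"),
#'     role = c("ligand", "receptor", "kinase", "kinase", "tf", "process")
#'   ),
#'   edges = data.frame(
#'     src  = c("IFNG", "IFNGR1", "JAK1", "STAT1", "TBX21"),
#'     dst  = c("IFNGR1", "JAK1", "STAT1", "TBX21", "Th1_diff"),
#'     sign = 1
#'   ),
#'   name = "Th1 differentiation (toy)"
#' )
#' enumerate_routes(p)$routes
pathway <- function(nodes, edges, routes = NULL, name = "pathway",
                    tf = NULL, up_targets = character(),
                    down_targets = character()) {
  nodes <- as_tibble(nodes)[, c("id", "role")]
  nodes$id <- as.character(nodes$id)
  nodes$role <- as.character(nodes$role)
  roles <- c("ligand", "receptor", "kinase", "tf", "target", "process")
  if (!all(nodes$role %in% roles)) {
    pd_abort(sprintf("unknown node role(s): %s",
                     paste(setdiff(nodes$role, roles), collapse = ", ")),
             "pd_pathway_error")
  }
  if (anyDuplicated(nodes$id)) {
    pd_abort("node ids must be unique within a pathway", "pd_pathway_error")
  }
  if (sum(nodes$role == "process") != 1) {
    pd_abort("a pathway must have exactly one biological-process node",
             "pd_pathway_error")
  }
  if (!any(nodes$role == "tf")) {
    pd_abort("a pathway must have at least one tf node", "pd_pathway_error")
  }
  process <- nodes$id[nodes$role == "process"]
  if (is.null(tf)) {
    tfs <- nodes$id[nodes$role == "tf"]
    if (length(tfs) > 1) {
      pd_abort("several tf nodes present; name the scoring TF via `tf`",
               "pd_pathway_error")
    }
    tf <- tfs
  } else if (!tf %in% nodes$id[nodes$role == "tf"]) {
    pd_abort(sprintf("`tf` = %s is not a declared tf node", tf),
             "pd_pathway_error")
  }

  edges <- as_tibble(edges)[, c("src", "dst", "sign")]
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  edges$sign <- as.numeric(edges$sign)
  bad <- setdiff(c(edges$src, edges$dst), nodes$id)
  if (length(bad) > 0) {
    pd_abort(sprintf("edge endpoint(s) not declared as nodes: %s",
                     paste(bad, collapse = ", ")), "pd_pathway_error")
  }
  if (!all(edges$sign %in% c(-1, 1))) {
    pd_abort("edge signs must be +1 (activation) or -1 (inhibition)",
             "pd_pathway_error")
  }
  if (any(edges$src == edges$dst)) {
    pd_abort("self-loops are not allowed", "pd_pathway_error")
  }
  if (anyDuplicated(paste(edges$src, edges$dst))) {
    pd_abort("duplicate (src, dst) edge", "pd_pathway_error")
  }

  p <- structure(
    list(name = name, nodes = nodes, edges = edges,
         routes = empty_routes(), tf = tf, process = process,
         up_targets = as.character(up_targets),
         down_targets = as.character(down_targets)),
    class = "pd_pathway"
  )
  if (!is.null(routes)) {
    p$routes <- build_routes(p, routes)
  }
  if (length(p$up_targets) > 0 || length(p$down_targets) > 0) {
    p <- extend_pathway(strip_targets(p), p$up_targets, p$down_targets)
  }
  p
}

empty_routes <- function() {
  tibble(route_id = character(), position = integer(),
         gene = character(), net_sign = numeric())
}

strip_targets <- function(p) {
  p$up_targets <- character()
  p$down_targets <- character()
  class(p) <- "pd_pathway"
  p
}

# routes argument normalisation: named list of gene vectors, or a data frame
# with route_id + genes list column; expanded to the long tibble with net signs
build_routes <- function(p, routes) {
  if (is.data.frame(routes)) {
    rl <- setNames(as.list(routes$genes), routes$route_id)
  } else {
    rl <- routes
    if (is.null(names(rl)) || any(names(rl) == "")) {
      names(rl) <- paste0("route_", seq_along(rl))
    }
  }
  out <- imap(rl, function(genes, rid) {
    genes <- as.character(genes)
    bad <- setdiff(genes, p$nodes$id)
    if (length(bad) > 0) {
      pd_abort(sprintf("route %s references unknown node(s): %s", rid,
                       paste(bad, collapse = ", ")), "pd_pathway_error")
    }
    if (genes[length(genes)] != p$tf) {
      pd_abort(sprintf("route %s must end at the TF (%s)", rid, p$tf),
               "pd_pathway_error")
    }
    tibble(route_id = rid, position = seq_along(genes), gene = genes,
           net_sign = route_net_signs(p, genes))
  })
  bind_rows(out)
}

#' Net signs of route genes toward the TF
#'
#' For an ordered gene chain `g1, ..., gk` ending at the TF, the net sign of
#' `g_i` is the product of the signs of the consecutive edges from `g_i` to
#' the TF. The TF itself gets net sign +1 by convention (it is excluded from
#' consistency counts anyway).
#'
#' @param p A `pd_pathway`.
#' @param genes Character vector, an ordered route ending at the TF.
#' @return Numeric vector of +/-1, one per gene.
#' @export
route_net_signs <- function(p, genes) {
  k <- length(genes)
  if (k == 1) return(1)
  esign <- setNames(p$edges$sign, paste(p$edges$src, p$edges$dst, sep = "\r"))
  step <- vapply(seq_len(k - 1), function(i) {
    key <- paste(genes[i], genes[i + 1], sep = "\r")
    s <- esign[[key]] %||% NA_real_
    if (is.na(s)) {
      pd_abort(sprintf("route step %s -> %s has no declared edge",
                       genes[i], genes[i + 1]), "pd_pathway_error")
    }
    s
  }, numeric(1))
  # net sign of g_i = product of edge signs from g_i to the TF
  c(rev(cumprod(rev(step))), 1)
}

#' Enumerate routes of an acyclic pathway
#'
#' Returns all simple directed paths from in-degree-0 nodes to the TF
#' (process node excluded), each annotated with per-gene net signs, in
#' lexicographic order of the node sequence. Used as a fallback when the
#' curation does not declare routes explicitly.
#'
#' @param p A `pd_pathway`.
#' @return The pathway with its `routes` tibble filled.
#' @export
enumerate_routes <- function(p) {
  stopifnot(inherits(p, "pd_pathway"))
  e <- filter(p$edges, .data$src != p$process, .data$dst != p$process)
  if (has_cycle(e)) {
    pd_abort(paste0("pathway contains a cycle; automatic route enumeration ",
                    "needs a DAG - declare routes explicitly"),
             "pd_cycle_error")
  }
  starts <- sort(setdiff(
    unique(c(e$src, e$dst, p$tf)),
    c(e$dst, p$process)
  ))
  succ <- split(e$dst, e$src)
  paths <- list()
  walk_paths <- function(node, acc) {
    if (node == p$tf) {
      paths[[length(paths) + 1]] <<- acc
      return(invisible())
    }
    for (nx in sort(succ[[node]] %||% character())) {
      if (!nx %in% acc) walk_paths(nx, c(acc, nx))
    }
  }
  for (s in starts) walk_paths(s, s)
  if (length(paths) == 0) {
    p$routes <- empty_routes()
    return(p)
  }
  ord <- order(vapply(paths, paste, character(1), collapse = "\r"))
  paths <- paths[ord]
  names(paths) <- paste0("route_", seq_along(paths))
  p$routes <- build_routes(p, paths)
  p
}

has_cycle <- function(edges) {
  nodes <- unique(c(edges$src, edges$dst))
  succ <- split(edges$dst, edges$src)
  state <- setNames(rep(0L, length(nodes)), nodes) # 0 unseen, 1 open, 2 done
  cyc <- FALSE
  visit <- function(v) {
    if (cyc || state[[v]] == 2L) return(invisible())
    if (state[[v]] == 1L) { cyc <<- TRUE; return(invisible()) }
    state[[v]] <<- 1L
    for (w in succ[[v]] %||% character()) visit(w)
    state[[v]] <<- 2L
  }
  for (v in nodes) visit(v)
  cyc
}

#' Extend a pathway with Up and Down target genes
#'
#' Attaches the classified target sets `G_u` (positively TF-correlated) and
#' `G_d` (negatively TF-correlated) downstream of the TF. The base topology
#' is untouched; target genes already on a route are dropped with a warning
#' so that route and target gene sets stay disjoint.
#'
#' @param p A `pd_pathway`.
#' @param up,down Character vectors of Up and Down target genes; must be
#'   disjoint.
#' @return A `pd_extended_pathway` (also a `pd_pathway`).
#' @export
extend_pathway <- function(p, up, down) {
  stopifnot(inherits(p, "pd_pathway"))
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both) > 0) {
    pd_abort(sprintf("gene(s) in both Up and Down target sets: %s",
                     paste(both, collapse = ", ")), "pd_target_overlap_error")
  }
  route_genes <- unique(p$routes$gene)
  clash <- intersect(c(up, down), route_genes)
  if (length(clash) > 0) {
    warn(sprintf("dropping target gene(s) already on a route: %s",
                 paste(clash, collapse = ", ")))
    up <- setdiff(up, clash)
    down <- setdiff(down, clash)
  }
  out <- strip_targets(p)
  out$up_targets <- up
  out$down_targets <- down
  class(out) <- c("pd_extended_pathway", "pd_pathway")
  out
}

#' Read a pathway from JSON or SIF
#'
#' The JSON layout mirrors the internal model: `name`, `nodes` (id, role),
#' `edges` (src, dst, sign), optional `routes` (id, genes), `tf`, `process`,
#' optional `up_targets` / `down_targets`. SIF carries only edges
#' (`src<TAB>activates|inhibits<TAB>dst`); node roles, the TF and the
#' process node are supplied through `tf` and `process`, and routes are not
#' expressible.
#'
#' @param path File path.
#' @param format `"json"` (default, inferred from extension) or `"sif"`.
#' @param tf,process For SIF input: the TF gene and the name of the
#'   biological-process node (added if absent from the edge list).
#' @return A `pd_pathway`.
#' @export
read_pathway <- function(path, format = NULL, tf = NULL, process = NULL) {
  if (!file.exists(path)) {
    pd_abort(sprintf("pathway file not found: %s", path), "pd_io_error")
  }
  format <- format %||%
    (if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "json")
  format <- match.arg(format, c("json", "sif"))
  if (format == "json") read_pathway_json(path) else {
    read_pathway_sif(path, tf = tf, process = process)
  }
}

read_pathway_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) {
                  pd_abort(sprintf("malformed pathway JSON (%s): %s",
                                   path, conditionMessage(e)), "pd_parse_error")
                })
  for (f in c("nodes", "edges")) {
    if (is.null(j[[f]])) {
      pd_abort(sprintf("pathway JSON missing field `%s`", f), "pd_parse_error")
    }
  }
  routes <- NULL
  raw <- jsonlite::read_json(path)
  if (!is.null(raw$routes) && length(raw$routes) > 0) {
    routes <- setNames(
      map(raw$routes, function(r) unlist(r$genes)),
      map_chr(raw$routes, function(r) r$id %||% ""))
  }
  pathway(nodes = j$nodes, edges = j$edges, routes = routes,
          name = j$name %||% "pathway", tf = j$tf,
          up_targets = unlist(j$up_targets) %||% character(),
          down_targets = unlist(j$down_targets) %||% character())
}

read_pathway_sif <- function(path, tf, process) {
  if (is.null(tf)) {
    pd_abort("SIF import needs `tf` (no roles in SIF)", "pd_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(map_int(recs, length) != 3)
  if (length(bad) > 0) {
    pd_abort(sprintf("malformed SIF record at line %d: %s", bad[1],
                     lines[bad[1]]), "pd_parse_error")
  }
  rel <- map_chr(recs, 2)
  if (!all(rel %in% c("activates", "inhibits"))) {
    i <- which(!rel %in% c("activates", "inhibits"))[1]
    pd_abort(sprintf("unknown SIF relation at line %d: %s", i, rel[i]),
             "pd_parse_error")
  }
  edges <- tibble(src = map_chr(recs, 1), dst = map_chr(recs, 3),
                  sign = ifelse(rel == "activates", 1, -1))
  ids <- unique(c(edges$src, edges$dst))
  process <- process %||% "biological_process"
  if (!process %in% ids) ids <- c(ids, process)
  if (!tf %in% ids) {
    pd_abort(sprintf("`tf` = %s not present in SIF edges", tf),
             "pd_parse_error")
  }
  nodes <- tibble(id = ids,
                  role = dplyr::case_when(ids == tf ~ "tf",
                                          ids == process ~ "process",
                                          TRUE ~ "kinase"))
  pathway(nodes = nodes, edges = edges,
          name = sub("\\.sif$", "", basename(path)), tf = tf)
}

#' Write a pathway to JSON
#'
#' Inverse of [read_pathway()]; `read_pathway(write_pathway(p, f))`
#' reproduces `p`.
#'
#' @param p A `pd_pathway`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(p, path) {
  stopifnot(inherits(p, "pd_pathway"))
  routes <- NULL
  if (nrow(p$routes) > 0) {
    rl <- split(p$routes$gene, p$routes$route_id)
    rl <- rl[unique(p$routes$route_id)]
    routes <- imap(rl, function(g, i) list(id = i, genes = as.list(g)))
    routes <- unname(routes)
  }
  obj <- list(name = p$name, nodes = p$nodes, edges = p$edges,
              routes = routes, tf = p$tf, process = p$process,
              up_targets = p$up_targets, down_targets = p$down_targets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @export
print.pd_pathway <- function(x, ...) {
  cat(sprintf("<pathway> %s\n", x$name))
  cat(sprintf("  %d nodes, %d edges; TF = %s; process = %s\n",
              nrow(x$nodes), nrow(x$edges), x$tf, x$process))
  nr <- length(unique(x$routes$route_id))
  cat(sprintf("  %d route(s)\n", nr))
  if (inherits(x, "pd_extended_pathway")) {
    cat(sprintf("  extended: %d Up, %d Down targets\n",
                length(x$up_targets), length(x$down_targets)))
  }
  invisible(x)
}

# genes of all routes, TF excluded (the scoring universe of Eq.-1-type scores)
route_gene_table <- function(p) {
  filter(p$routes, .data$gene != p$tf)
}
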