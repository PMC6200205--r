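#' Construct and validate a connectome table
#'
#' A connectome table declares the cell types of the model eye and the typed
#' connections between them. Cell types belong to one of four stages
#' (photoreceptor, lamina, medulla, lobula) and carry a hierarchy rank:
#' photoreceptors are rank 0 and information may only flow from lower to
#' higher rank, which makes the induced graph a DAG with photoreceptors as its
#' only sources. Each connection carries the side length, in retinotopic
#' columns, of the locally connected receptive field it is compiled into.
#'
#' Structural rules enforced (an invalid table is rejected with an error):
#' \itemize{
#'   \item type names unique; stages valid; ranks non-negative integers;
#'     photoreceptors have rank 0;
#'   \item no self connections between a type and itself, and no connections
#'     between two lamina monopolar "L" types (e.g. L1 and L2);
#'   \item no upstream connections: \code{rank(pre) < rank(post)};
#'   \item receptive-field sizes are odd positive integers;
#'   \item every connection endpoint is a declared type;
#'   \item photoreceptors are the only sources (every non-photoreceptor type
#'     has at least one afferent);
#'   \item at least one lobula type is reachable from every photoreceptor.
#' }
#'
#' @param cell_types data.frame with columns \code{name}, \code{stage},
#'   \code{rank}.
#' @param connections data.frame with columns \code{pre}, \code{post},
#'   \code{rf_columns}.
#' @return An object of class \code{connectome_table}.
#' @seealso [load_connectome()] to read one from CSV, [build_network()] to
#'   compile it.
#' @export
connectome_table <- function(cell_types, connections) {
  stages <- c("photoreceptor", "lamina", "medulla", "lobula")
  ct <- as.data.frame(cell_types, stringsAsFactors = FALSE)
  cn <- as.data.frame(connections, stringsAsFactors = FALSE)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  need(ct, c("name", "stage", "rank"), "cell_types")
  need(cn, c("pre", "post", "rf_columns"), "connections")

  ct$name <- as.character(ct$name)
  ct$stage <- as.character(ct$stage)
  ct$rank <- as.integer(ct$rank)
  cn$pre <- as.character(cn$pre)
  cn$post <- as.character(cn$post)
  cn$rf_columns <- as.integer(cn$rf_columns)

  if (anyDuplicated(ct$name))
    stop("duplicate cell type name(s): ",
         paste(unique(ct$name[duplicated(ct$name)]), collapse = ", "))
  bad_stage <- setdiff(unique(ct$stage), stages)
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  if (any(is.na(ct$rank)) || any(ct$rank < 0))
    stop("ranks must be non-negative integers")
  pr <- ct$stage == "photoreceptor"
  if (!any(pr)) stop("table declares no photoreceptor type")
  if (any(ct$rank[pr] != 0L))
    stop("photoreceptor types must have rank 0: ",
         paste(ct$name[pr & ct$rank != 0L], collapse = ", "))

  unknown <- setdiff(c(cn$pre, cn$post), ct$name)
  if (length(unknown))
    stop("connection references undeclared cell type(s): ",
         paste(unique(unknown), collapse = ", "))

  if (any(is.na(cn$rf_columns)) || any(cn$rf_columns < 1) ||
      any(cn$rf_columns %% 2 != 1))
    stop("rf_columns must be odd positive integers")

  rank_of <- setNames(ct$rank, ct$name)
  stage_of <- setNames(ct$stage, ct$name)

  self <- cn$pre == cn$post
  is_L <- function(x) stage_of[x] == "lamina" & grepl("^L[0-9]+$", x)
  lam_lam <- is_L(cn$pre) & is_L(cn$post)
  if (any(self | lam_lam)) {
    i <- which(self | lam_lam)[1]
    stop("no connections between ", cn$pre[i], " and ", cn$post[i],
         " (self connections within a neuron subtype family are not allowed)")
  }
  up <- rank_of[cn$pre] >= rank_of[cn$post]
  if (any(up)) {
    i <- which(up)[1]
    stop("upstream connection ", cn$pre[i], " -> ", cn$post[i],
         ": rank(", cn$pre[i], ") = ", rank_of[cn$pre[i]],
         " must be lower than rank(", cn$post[i], ") = ", rank_of[cn$post[i]])
  }
  if (anyDuplicated(cn[, c("pre", "post")]))
    stop("duplicate connection(s) between the same pre/post pair")

  no_in <- setdiff(ct$name[!pr], cn$post)
  if (length(no_in))
    stop("non-photoreceptor type(s) with no afferent connection: ",
         paste(no_in, collapse = ", "),
         " (photoreceptors must be the only sources)")
  ph_in <- intersect(ct$name[pr], cn$post)
  if (length(ph_in))
    stop("photoreceptor type(s) receive connections: ",
         paste(ph_in, collapse = ", "))

  # reachability: each photoreceptor must reach at least one lobula type
  adj <- split(cn$post, cn$pre)
  reaches_lobula <- function(src) {
    seen <- character(0); frontier <- src
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      if (any(stage_of[nxt] == "lobula")) return(TRUE)
      seen <- c(seen, nxt); frontier <- nxt
    }
    FALSE
  }
  for (p in ct$name[pr])
    if (!reaches_lobula(p))
      stop("photoreceptor ", p, " cannot reach any lobula type")

  structure(list(cell_types = ct, connections = cn),
            class = "connectome_table")
}

#' Read a connectome table from CSV
#'
#' The file has two `#`-prefixed sections: a \code{#types} section with rows
#' \code{name,stage,rank}, then an \code{#edges} section with rows
#' \code{pre,post,rf_columns}. See [default_connectome_path()] for the table
#' shipped with the package.
#'
#' @param path CSV file path.
#' @return A validated [connectome_table()].
#' @examples
#' tab <- load_connectome(default_connectome_path())
#' nrow(tab$cell_types)  # 30 cell types
#' @export
load_connectome <- function(path) {
  if (!file.exists(path)) stop("connectome file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  t_at <- which(lines == "#types")
  e_at <- which(lines == "#edges")
  if (length(t_at) != 1L || length(e_at) != 1L || e_at < t_at)
    stop("connectome CSV must contain one '#types' section followed by one ",
         "'#edges' section")
  parse_block <- function(block, what) {
    if (length(block) < 2L) stop("empty '", what, "' section")
    read.csv(text = paste(block, collapse = "\n"), stringsAsFactors = FALSE,
             strip.white = TRUE)
  }
  types <- parse_block(lines[(t_at + 1):(e_at - 1)], "#types")
  edges <- parse_block(lines[(e_at + 1):length(lines)], "#edges")
  connectome_table(types, edges)
}

#' Write a connectome table to the two-section CSV format
#'
#' @param table a [connectome_table()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_connectome <- function(table, path) {
  stopifnot(inherits(table, "connectome_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#types", con)
  write.csv(table$cell_types, con, row.names = FALSE, quote = FALSE)
  writeLines("#edges", con)
  write.csv(table$connections, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.connectome_table <- function(x, ...) {
  st <- table(factor(x$cell_types$stage,
                     c("photoreceptor", "lamina", "medulla", "lobula")))
  cat("<connectome_table> ", nrow(x$cell_types), " cell types (",
      paste(sprintf("%s %d", names(st), st), collapse = ", "), "), ",
      nrow(x$connections), " connections; rf sizes {",
      paste(sort(unique(x$connections$rf_columns)), collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

# topological evaluation order: by (rank, name) — deterministic tie-break
topo_order <- function(table) {
  ct <- table$cell_types
  ct$name[order(ct$rank, ct$name)]
}
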