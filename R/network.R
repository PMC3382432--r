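#' Construct a causal network from an edge data frame
#'
#' A causal network is a directed, signed graph of regulator -> regulatee
#' relationships derived from perturbation experiments reported in the
#' literature. Each edge asserts that perturbing the regulator causally
#' changes the transcript level of the regulatee, either upward
#' (`sign = "up"`) or downward (`sign = "down"`).
#'
#' Duplicate (regulator, regulatee) pairs are collapsed to one edge. When the
#' same pair is asserted with both signs, the conflict is resolved by keeping
#' a single edge with sign `"up"` and emitting a warning: the sign never
#' enters the coherence scores (which use absolute correlations throughout),
#' it only labels the up/down partition in the results table.
#'
#' Regulator identifiers are opaque strings; entities measured at the
#' protein or modification level are expected to be collapsed to a single
#' node id upstream. Identifiers carrying a `CHEM:` or `ENV:` prefix are
#' parsed normally but flagged as chemical/environmental regulators, which
#' [score_all()] excludes from reports by default.
#'
#' @param edges data frame with columns `regulator`, `regulatee`, `sign`
#'   (`"up"`/`"down"`) and optionally `citation`.
#' @return An object of class `causal_network`: a list with an `edges` data
#'   frame (columns `regulator`, `regulatee`, `sign`, `citation`,
#'   `chemical`) and a logical `filtered` flag.
#' @seealso [load_network()], [filter_network()], [out_degree()]
#' @export
causal_network <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("regulator", "regulatee", "sign") %in% names(edges)))
  if (is.null(edges$citation)) edges$citation <- rep(NA_character_, nrow(edges))
  edges <- data.frame(regulator = as.character(edges$regulator),
                      regulatee = as.character(edges$regulatee),
                      sign = as.character(edges$sign),
                      citation = as.character(edges$citation),
                      stringsAsFactors = FALSE)
  bad <- !edges$sign %in% c("up", "down")
  if (any(bad)) stop("invalid sign token(s): ",
                     paste(unique(edges$sign[bad]), collapse = ", "))
  # collapse duplicate pairs; resolve sign conflicts to "up"
  key <- paste(edges$regulator, edges$regulatee, sep = "\r")
  if (anyDuplicated(key)) {
    n_signs <- tapply(edges$sign, key, function(s) length(unique(s)))
    conflicted <- names(n_signs)[n_signs > 1]
    if (length(conflicted)) {
      warning(length(conflicted),
              " regulator/regulatee pair(s) asserted with both signs; ",
              "keeping a single edge with sign 'up'")
      edges$sign[key %in% conflicted] <- "up"
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges$chemical <- grepl("^(CHEM|ENV):", edges$regulator)
  rownames(edges) <- NULL
  structure(list(edges = edges, filtered = FALSE), class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("causal_network: %d edges, %d regulators, %d regulatees%s\n",
              nrow(x$edges), length(regulators(x)), length(regulatees(x)),
              if (isTRUE(x$filtered)) " (filtered)" else ""))
  invisible(x)
}

#' Regulator and regulatee identifier sets
#'
#' @param net a `causal_network`.
#' @return Character vector of distinct ids (a gene may appear in both
#'   roles).
#' @export
regulators <- function(net) unique(net$edges$regulator)

#' @rdname regulators
#' @export
regulatees <- function(net) unique(net$edges$regulatee)

#' Read a causal network from a tab-separated edge list
#'
#' The dialect is 3-4 tab-separated columns per line: regulator, regulatee,
#' sign (`up`/`down`) and an optional free-text citation tag. Lines starting
#' with `#` and blank lines are ignored. Rows with fewer than 3 fields or an
#' unknown sign token are rejected with a warning naming the line numbers;
#' duplicate pairs are collapsed as in [causal_network()]. Self-loops are
#' kept at load time (they are reported, and removed by [filter_network()]).
#'
#' @param path path to the edge-list file.
#' @return A `causal_network` with all accepted edges.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("cannot read network file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty network file: ", path)
    return(causal_network(data.frame(regulator = character(),
                                     regulatee = character(),
                                     sign = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  short <- nf < 3
  if (any(short))
    warning("rejected ", sum(short), " row(s) with < 3 fields at line(s): ",
            paste(utils::head(lineno[short], 10), collapse = ", "))
  fields <- fields[!short]
  lineno <- lineno[!short]
  reg <- vapply(fields, `[`, "", 1L)
  tgt <- vapply(fields, `[`, "", 2L)
  sgn <- vapply(fields, `[`, "", 3L)
  cit <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  badsign <- !sgn %in% c("up", "down")
  if (any(badsign))
    warning("rejected ", sum(badsign), " row(s) with unknown sign token at ",
            "line(s): ", paste(utils::head(lineno[badsign], 10), collapse = ", "))
  ok <- !badsign
  net <- causal_network(data.frame(regulator = reg[ok], regulatee = tgt[ok],
                                   sign = sgn[ok], citation = cit[ok],
                                   stringsAsFactors = FALSE))
  nself <- sum(net$edges$regulator == net$edges$regulatee)
  if (nself) message(nself, " self-loop edge(s) present; filter_network() removes them")
  net
}

#' Write a causal network as a tab-separated edge list
#'
#' Inverse of [load_network()]: writes regulator, regulatee, sign and
#' citation (blank when missing) columns, one edge per line.
#'
#' @param net a `causal_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  e <- net$edges
  cit <- ifelse(is.na(e$citation), "", e$citation)
  writeLines(paste(e$regulator, e$regulatee, e$sign, cit, sep = "\t"), path)
  invisible(path)
}

#' Filter a causal network against the measured gene universe
#'
#' Applies, in order: (1) removal of self-regulation edges; (2) restriction
#' of regulatees to the `expressed` gene set (regulatees without a measured
#' transcript cannot contribute to coherence); (3) removal of regulators left
#' with fewer than 2 regulatees, since coherence is defined over regulatee
#' pairs. The operation is idempotent.
#'
#' @param net a `causal_network`.
#' @param expressed non-empty character vector of measured gene ids.
#' @return The filtered `causal_network` (possibly with zero edges).
#' @export
filter_network <- function(net, expressed) {
  stopifnot(length(expressed) > 0)
  e <- net$edges
  e <- e[e$regulator != e$regulatee, , drop = FALSE]
  e <- e[e$regulatee %in% expressed, , drop = FALSE]
  deg <- table(e$regulator)
  e <- e[e$regulator %in% names(deg)[deg >= 2], , drop = FALSE]
  rownames(e) <- NULL
  out <- structure(list(edges = e, filtered = TRUE), class = "causal_network")
  out
}

#' Out-degree of a regulator
#'
#' The number of distinct regulatees of a regulator; the ranking statistic
#' of the degree-based baseline ([degree_rank_baseline()]).
#'
#' @param net a `causal_network`.
#' @param regulator a single regulator id present in the network.
#' @return Integer out-degree.
#' @export
out_degree <- function(net, regulator) {
  if (!regulator %in% net$edges$regulator)
    stop("unknown regulator: ", regulator)
  sum(net$edges$regulator == regulator)
}

#' Regulatee lists per regulator
#'
#' @param net a `causal_network`.
#' @return Named list mapping each regulator id to the character vector of
#'   its regulatees.
#' @export
regulatee_sets <- function(net) {
  split(net$edges$regulatee, net$edges$regulator)
}

#' Summarize a causal network as JSON
#'
#' Writes (or returns) a small JSON report with node/edge counts and the
#' out-degree histogram.
#'
#' @param net a `causal_network`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
network_summary <- function(net, path = NULL) {
  deg <- table(table(net$edges$regulator))
  rep <- list(
    n_edges = nrow(net$edges),
    n_regulators = length(regulators(net)),
    n_regulatees = length(regulatees(net)),
    n_chemical_regulators = length(unique(net$edges$regulator[net$edges$chemical %||% FALSE])),
    filtered = isTRUE(net$filtered),
    out_degree_histogram = list(degree = as.integer(names(deg)),
                                count = as.integer(deg))
  )
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of weakly connected components
#'
#' Counts weak components over the nodes incident to at least one edge,
#' treating every edge as undirected.
#'
#' @param net a `causal_network`.
#' @return Integer component count (0 for an empty network).
#' @export
weak_components <- function(net) {
  e <- net$edges
  if (!nrow(e)) return(0L)
  ids <- unique(c(e$regulator, e$regulatee))
  cpp_weak_components(match(e$regulator, ids), match(e$regulatee, ids),
                      length(ids))
}
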