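#' Construct a catchment object
#'
#' A catchment bundles the dendritic river network (segments between nodes)
#' with its point sources (wastewater treatment plants, hospitals), flow
#' gauges and monitoring sites.  Segments are directed edges `from_node ->
#' to_node`; water drains towards a single outlet.  All spatial coordinates
#' are planar metres in an arbitrary projected CRS; no geodesy is performed
#' (distances only feed the closest-plant search in re-routing scenarios).
#'
#' @param segments data.frame with columns `segment_id`, `from_node`,
#'   `to_node`, `length` (m, at most 2000), `mq`, `mnq`, `q50` (m3/s,
#'   `mnq <= q50 <= mq`), `v_ref` (m/s), `v_exponent` (dimensionless, in
#'   `[0,1)`), `x`, `y` (segment midpoint).  An optional `local_mq` column
#'   carries the segment's own runoff contribution.
#' @param nodes data.frame with columns `node_id`, `x`, `y`.
#' @param wwtps data.frame with columns `wwtp_id`, `discharge_node`,
#'   `population_connected`, `treatment_category` (one of `"lagoon"`,
#'   `"constructed_wetland"`, `"bio_filter"`, `"activated_sludge"`),
#'   `effluent_flow` (m3/d, `NA` = derive from population), `x`, `y`.
#' @param hospitals data.frame with columns `hospital_id`, `receiving_wwtp`,
#'   `patients_per_year`, `beds`, `department_flags` (semicolon-separated
#'   labels such as `"radiology"`, may be empty).  Hospital wastewater is
#'   always routed through its receiving plant, never straight to the river.
#' @param gauges data.frame with columns `gauge_id`, `node`, `observed_mq`
#'   (m3/s), `observed_mnq` (optional, `NA` allowed).
#' @param monitoring_sites data.frame with columns `site_id`, `node`.
#'
#' @return An object of class `catchment`.
#' @seealso [validate_catchment()], [topological_order()], [read_catchment()]
#' @export
catchment <- function(segments, nodes,
                      wwtps = NULL, hospitals = NULL,
                      gauges = NULL, monitoring_sites = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("segment_id", "from_node", "to_node", "length",
            "mq", "mnq", "q50", "v_ref", "v_exponent", "x", "y")
  miss <- setdiff(need, names(segments))
  if (length(miss) > 0)
    stop("segments is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(c("node_id", "x", "y") %in% names(nodes)))
    stop("nodes must have columns node_id, x, y")
  if (!("local_mq" %in% names(segments))) segments$local_mq <- NA_real_
  for (col in c("segment_id", "from_node", "to_node"))
    segments[[col]] <- as.character(segments[[col]])
  nodes$node_id <- as.character(nodes$node_id)

  wwtps <- .default_df(wwtps, list(
    wwtp_id = character(), discharge_node = character(),
    population_connected = numeric(), treatment_category = character(),
    effluent_flow = numeric(), x = numeric(), y = numeric()))
  wwtps$wwtp_id <- as.character(wwtps$wwtp_id)
  wwtps$discharge_node <- as.character(wwtps$discharge_node)
  if (!("effluent_flow" %in% names(wwtps))) wwtps$effluent_flow <- NA_real_

  hospitals <- .default_df(hospitals, list(
    hospital_id = character(), receiving_wwtp = character(),
    patients_per_year = numeric(), beds = numeric(),
    department_flags = character()))
  hospitals$hospital_id <- as.character(hospitals$hospital_id)
  hospitals$receiving_wwtp <- as.character(hospitals$receiving_wwtp)
  if (!("department_flags" %in% names(hospitals)))
    hospitals$department_flags <- ""
  hospitals$department_flags[is.na(hospitals$department_flags)] <- ""

  gauges <- .default_df(gauges, list(
    gauge_id = character(), node = character(),
    observed_mq = numeric(), observed_mnq = numeric()))
  gauges$gauge_id <- as.character(gauges$gauge_id)
  gauges$node <- as.character(gauges$node)
  if (!("observed_mnq" %in% names(gauges))) gauges$observed_mnq <- NA_real_

  monitoring_sites <- .default_df(monitoring_sites, list(
    site_id = character(), node = character()))
  monitoring_sites$site_id <- as.character(monitoring_sites$site_id)
  monitoring_sites$node <- as.character(monitoring_sites$node)

  structure(list(segments = segments, nodes = nodes, wwtps = wwtps,
                 hospitals = hospitals, gauges = gauges,
                 monitoring_sites = monitoring_sites),
            class = "catchment")
}

.default_df <- function(x, proto) {
  if (is.null(x)) return(as.data.frame(proto, stringsAsFactors = FALSE))
  as.data.frame(x, stringsAsFactors = FALSE)
}

#' @export
print.catchment <- function(x, ...) {
  cat(sprintf(
    "<catchment> %d segments, %d nodes, %d WWTPs, %d hospitals, %d gauges, %d monitoring sites\n",
    nrow(x$segments), nrow(x$nodes), nrow(x$wwtps),
    nrow(x$hospitals), nrow(x$gauges), nrow(x$monitoring_sites)))
  cat(sprintf("  total flow length: %.1f km\n", sum(x$segments$length) / 1000))
  invisible(x)
}

#' Validate a catchment against its structural invariants
#'
#' Checks every type invariant (segment lengths, flow ordering
#' `MNQ <= Q50 <= MQ`, velocity parameters, treatment categories, gauge
#' flows) and the topology invariants (no flow splits, acyclic, a single
#' outlet, all referenced nodes and plants exist).  Violations are data, not
#' errors: an invalid catchment yields a non-empty report, never an
#' exception, so loaders can show all problems at once.
#'
#' @param ct A [catchment()].
#' @return A data.frame with columns `entity`, `id`, `rule`; zero rows iff
#'   the catchment is valid.
#' @export
validate_catchment <- function(ct) {
  stopifnot(inherits(ct, "catchment"))
  v <- list()
  add <- function(entity, id, rule)
    v[[length(v) + 1]] <<- data.frame(entity = entity, id = id, rule = rule,
                                      stringsAsFactors = FALSE)
  sg <- ct$segments
  if (anyDuplicated(sg$segment_id))
    add("segment", sg$segment_id[duplicated(sg$segment_id)][1],
        "duplicate segment_id")
  for (i in seq_len(nrow(sg))) {
    s <- sg[i, ]
    if (!is.finite(s$length) || s$length <= 0 || s$length > 2000)
      add("segment", s$segment_id, "length not in (0, 2000] m")
    if (!is.finite(s$mq) || !is.finite(s$mnq) || !is.finite(s$q50) ||
        s$mnq < 0 || s$mnq > s$q50 || s$q50 > s$mq)
      add("segment", s$segment_id, "flow ordering 0 <= mnq <= q50 <= mq violated")
    if (!is.finite(s$v_ref) || s$v_ref <= 0)
      add("segment", s$segment_id, "v_ref must be > 0")
    if (!is.finite(s$v_exponent) || s$v_exponent < 0 || s$v_exponent >= 1)
      add("segment", s$segment_id, "v_exponent not in [0, 1)")
    if (identical(s$from_node, s$to_node))
      add("segment", s$segment_id, "self-loop (from_node == to_node)")
    if (!is.na(s$local_mq) && s$local_mq < 0)
      add("segment", s$segment_id, "local_mq must be >= 0")
  }
  node_ids <- ct$nodes$node_id
  bad_ref <- !(c(sg$from_node, sg$to_node) %in% node_ids)
  if (any(bad_ref))
    for (nd in unique(c(sg$from_node, sg$to_node)[bad_ref]))
      add("node", nd, "segment references unknown node")

  # flow splits: a node may feed at most one downstream segment
  out_deg <- table(sg$from_node)
  for (nd in names(out_deg)[out_deg > 1])
    add("node", nd, "flow split (out-degree > 1) not supported")

  # cycle / outlet structure on the segment graph
  if (nrow(sg) > 0) {
    ord <- tryCatch(topological_order(ct), error = function(e) NULL)
    if (is.null(ord)) {
      add("catchment", "-", "graph not acyclic")
    } else {
      outlets <- setdiff(sg$to_node, sg$from_node)
      if (length(outlets) != 1)
        add("catchment", "-",
            sprintf("expected exactly 1 outlet, found %d", length(outlets)))
    }
  }

  for (i in seq_len(nrow(ct$wwtps))) {
    w <- ct$wwtps[i, ]
    if (!(w$discharge_node %in% node_ids))
      add("wwtp", w$wwtp_id, "discharge_node not in network")
    if (!is.finite(w$population_connected) || w$population_connected < 0)
      add("wwtp", w$wwtp_id, "population_connected must be >= 0")
    if (!(w$treatment_category %in% treatment_categories()))
      add("wwtp", w$wwtp_id,
          paste0("unknown treatment_category '", w$treatment_category, "'"))
    if (!is.na(w$effluent_flow) && w$effluent_flow < 0)
      add("wwtp", w$wwtp_id, "effluent_flow must be >= 0")
  }
  if (anyDuplicated(ct$wwtps$wwtp_id))
    add("wwtp", ct$wwtps$wwtp_id[duplicated(ct$wwtps$wwtp_id)][1],
        "duplicate wwtp_id")
  for (i in seq_len(nrow(ct$hospitals))) {
    h <- ct$hospitals[i, ]
    if (!(h$receiving_wwtp %in% ct$wwtps$wwtp_id))
      add("hospital", h$hospital_id, "receiving_wwtp unknown")
    if (!is.finite(h$patients_per_year) || h$patients_per_year < 0)
      add("hospital", h$hospital_id, "patients_per_year must be >= 0")
  }
  for (i in seq_len(nrow(ct$gauges))) {
    g <- ct$gauges[i, ]
    if (!(g$node %in% node_ids))
      add("gauge", g$gauge_id, "gauge node not in network")
    if (!is.finite(g$observed_mq) || g$observed_mq <= 0)
      add("gauge", g$gauge_id, "observed_mq must be > 0")
  }
  for (i in seq_len(nrow(ct$monitoring_sites))) {
    m <- ct$monitoring_sites[i, ]
    if (!(m$node %in% node_ids))
      add("monitoring_site", m$site_id, "site node not in network")
  }
  if (length(v) == 0)
    return(data.frame(entity = character(), id = character(),
                      rule = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Allowed wastewater treatment categories
#'
#' @return Character vector of the four supported treatment categories.
#' @export
treatment_categories <- function() {
  c("lagoon", "constructed_wetland", "bio_filter", "activated_sludge")
}

#' Topological order of the river segments
#'
#' Orders segments so that every segment appears after all segments upstream
#' of it (headwaters first, outlet last).  Deterministic: among segments
#' whose upstream sides are all emitted, the smallest `segment_id` goes
#' first (Kahn's algorithm with an ordered frontier).
#'
#' @param ct A [catchment()].
#' @return Character vector of `segment_id`s, a permutation of
#'   `ct$segments$segment_id`.
#' @export
topological_order <- function(ct) {
  stopifnot(inherits(ct, "catchment"))
  sg <- ct$segments
  n <- nrow(sg)
  if (n == 0) return(character())
  # segment i depends on all segments whose to_node == from_node[i]
  up <- .upstream_index(sg)
  indeg <- vapply(up, length, integer(1))
  down <- vector("list", n)
  for (i in seq_len(n)) for (j in up[[i]])
    down[[j]] <- c(down[[j]], i)
  frontier <- which(indeg == 0L)
  frontier <- frontier[order(sg$segment_id[frontier])]
  ord <- integer(0)
  while (length(frontier) > 0) {
    i <- frontier[1]
    frontier <- frontier[-1]
    ord <- c(ord, i)
    for (j in down[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) {
        frontier <- c(frontier, j)
        frontier <- frontier[order(sg$segment_id[frontier])]
      }
    }
  }
  if (length(ord) != n)
    stop("cycle detected in river network; no topological order exists")
  sg$segment_id[ord]
}

# list: for each segment row, integer indices of its direct upstream segments
.upstream_index <- function(sg) {
  by_to <- split(seq_len(nrow(sg)), sg$to_node)
  lapply(sg$from_node, function(fn) {
    idx <- by_to[[fn]]
    if (is.null(idx)) integer(0) else idx
  })
}

# indices of segments whose from_node == node (at most 1 in a valid catchment)
.segments_from_node <- function(sg, node) which(sg$from_node == node)

# The segment a monitoring site or gauge observes: prefer the segment
# starting at the node (concentration after complete mixing), fall back to
# the segment ending there (outlet sites).
.segment_at_node <- function(sg, node) {
  i <- which(sg$from_node == node)
  if (length(i) >= 1) return(i[1])
  i <- which(sg$to_node == node)
  if (length(i) >= 1) return(i[order(sg$segment_id[i])][1])
  NA_integer_
}
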