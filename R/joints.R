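# Joint naming, the 32 -> 25 joint selection, and the 25-node skeletal graph.
#
# The raw capture convention is the 32-joint depth-camera body-tracking
# skeleton; analysis uses 25 of those joints re-indexed 0..24 (sacrum first,
# right thumb last), with the face joints and clavicles dropped. Both the
# selection map and the edge list are configuration (JSON), not hard-coded
# at the call sites; the defaults below are shipped in inst/extdata.

RAW32_JOINT_NAMES <- c(
  "pelvis", "spine_navel", "spine_chest", "neck",
  "clavicle_left", "shoulder_left", "elbow_left", "wrist_left",
  "hand_left", "handtip_left", "thumb_left",
  "clavicle_right", "shoulder_right", "elbow_right", "wrist_right",
  "hand_right", "handtip_right", "thumb_right",
  "hip_left", "knee_left", "ankle_left", "foot_left",
  "hip_right", "knee_right", "ankle_right", "foot_right",
  "head", "nose", "eye_left", "ear_left", "eye_right", "ear_right"
)

SELECTED25_JOINT_NAMES <- c(
  "sacrum", "spine_center", "neck", "head",
  "shoulder_left", "elbow_left", "wrist_left", "hand_left",
  "shoulder_right", "elbow_right", "wrist_right", "hand_right",
  "hip_left", "knee_left", "ankle_left", "foot_left",
  "hip_right", "knee_right", "ankle_right", "foot_right",
  "shoulder_center", "handtip_left", "thumb_left",
  "handtip_right", "thumb_right"
)

# selection_map[k] = 0-based raw index feeding selected joint k-1.
# Dropped raw joints: clavicles, nose, both eyes, both ears (7 of 32).
DEFAULT_SELECTION_MAP <- c(
  0L, 1L, 3L, 26L,            # sacrum, spine center, neck, head
  5L, 6L, 7L, 8L,             # left arm
  12L, 13L, 14L, 15L,         # right arm
  18L, 19L, 20L, 21L,         # left leg
  22L, 23L, 24L, 25L,         # right leg
  2L,                         # shoulder center (chest)
  9L, 10L,                    # left hand tip / thumb
  16L, 17L                    # right hand tip / thumb
)

# 24 undirected edges forming the anatomical tree over the 25 joints
# (0-based pairs, parent first: parent is the trunk-ward endpoint).
DEFAULT_EDGES <- matrix(c(
  0L, 1L,   1L, 20L,  20L, 2L,   2L, 3L,
  20L, 4L,  4L, 5L,   5L, 6L,   6L, 7L,   7L, 21L,  7L, 22L,
  20L, 8L,  8L, 9L,   9L, 10L,  10L, 11L, 11L, 23L, 11L, 24L,
  0L, 12L,  12L, 13L, 13L, 14L, 14L, 15L,
  0L, 16L,  16L, 17L, 17L, 18L, 18L, 19L
), ncol = 2, byrow = TRUE)

#' The 25-node skeletal graph
#'
#' Nodes follow the analysis indexing (0 = sacrum ... 24 = right thumb);
#' edges are the anatomical tree (24 undirected edges). The object also
#' carries the default 32 -> 25 selection map used by [select_joints()].
#'
#' @param node_names Character vector of 25 node labels.
#' @param edges Integer matrix (n_edges x 2) of 0-based node pairs.
#' @param selection_map Integer vector of 25 raw 0-based indices.
#' @return A `joint_graph` object.
#' @export
joint_graph <- function(node_names = SELECTED25_JOINT_NAMES,
                        edges = DEFAULT_EDGES,
                        selection_map = DEFAULT_SELECTION_MAP) {
  n <- length(node_names)
  sg_assert(is.matrix(edges) && ncol(edges) == 2, "edges must be an n x 2 matrix")
  sg_assert(all(edges >= 0) && all(edges < n), "edge endpoints out of range")
  sg_assert(all(edges[, 1] != edges[, 2]), "self-edges are not allowed")
  structure(list(
    node_count = n,
    node_names = node_names,
    edges = edges,
    selection_map = as.integer(selection_map)
  ), class = "joint_graph")
}

graph_is_connected_tree <- function(graph) {
  n <- graph$node_count
  e <- graph$edges
  if (nrow(e) != n - 1) return(FALSE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1] + 1L; b <- e[i, 2] + 1L
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

hop_distance_from <- function(graph, root0 = 0L) {
  n <- graph$node_count
  adj <- matrix(FALSE, n, n)
  adj[graph$edges + 1L] <- TRUE
  adj[graph$edges[, 2:1, drop = FALSE] + 1L] <- TRUE
  d <- rep(NA_integer_, n); d[root0 + 1L] <- 0L
  frontier <- root0 + 1L; k <- 0L
  while (length(frontier)) {
    k <- k + 1L
    nxt <- which(is.na(d) & apply(adj[, frontier, drop = FALSE], 1, any))
    d[nxt] <- k
    frontier <- nxt
  }
  d
}

#' Read / write a joint-graph configuration (JSON)
#'
#' The editable topology file lists `node_names`, `edges` (0-based pairs)
#' and the 32 -> 25 `selection_map`.
#'
#' @param path JSON file path.
#' @return `read_joint_graph` returns a [joint_graph()].
#' @export
read_joint_graph <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  joint_graph(node_names = j$node_names,
              edges = matrix(as.integer(j$edges_flat), ncol = 2, byrow = TRUE),
              selection_map = as.integer(j$selection_map))
}

#' @rdname read_joint_graph
#' @param graph A [joint_graph()].
#' @export
write_joint_graph <- function(graph, path) {
  jsonlite::write_json(list(
    node_names = graph$node_names,
    edges_flat = as.integer(t(graph$edges)),
    selection_map = graph$selection_map
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
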