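# Density-based spatial clustering (DBSCAN), Euclidean metric.
#
# Distance-matrix variant suited to the small point clouds handled here
# (a few hundred conjunctive trials per response distribution). A point is
# a core point if at least `min_pts` points (counting itself) lie within
# `eps`; clusters are the connected components of core points under the
# eps-neighbour relation, with non-core neighbours of a core point attached
# as border points (first-come assignment). Returns integer labels, 0 for
# noise.
dbscan_labels <- function(D, eps, min_pts = 5) {
  dbscan_labels_cpp(D, eps, as.integer(min_pts))
}

# Pairwise Euclidean distance matrix of an n x 2 matrix.
dist_matrix <- function(points) {
  as.matrix(dist(points))
}
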