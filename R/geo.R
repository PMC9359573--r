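#' Merge trap sites within a haversine radius
#'
#' Combines sites collected within `radius_km` of each other by
#' single-linkage: sites are nodes, pairs at haversine distance no greater
#' than the radius are edges, and each connected component becomes one
#' cluster, so chains of nearby sites merge transitively. Distances use a
#' spherical Earth of radius 6371.0088 km. Cluster ids are the
#' lexicographically smallest member site id, which makes the result
#' invariant to input order.
#'
#' @param sites Data frame with columns `site_id`, `latitude`, `longitude`.
#' @param radius_km Linkage radius in kilometres (> 0).
#' @return Data frame with `site_id` and `cluster_id`.
#' @export
#' @examples
#' sites <- data.frame(site_id = c("A", "B", "C"),
#'                     latitude = c(37.70, 37.705, 37.80),
#'                     longitude = c(-122.1, -122.1, -122.1))
#' merge_sites(sites)
merge_sites <- function(sites, radius_km = 1.0) {
  stopifnot(all(c("site_id", "latitude", "longitude") %in% names(sites)),
            radius_km > 0)
  if (any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180))
    stop("invalid coordinates")
  sites <- sites[!duplicated(sites$site_id), , drop = FALSE]
  n <- nrow(sites)
  coords <- cbind(sites$longitude, sites$latitude)
  d_m <- geosphere::distm(coords, fun = function(x, y)
    geosphere::distHaversine(x, y, r = 6371008.8))
  adj <- d_m <= radius_km * 1000
  # connected components by breadth-first search
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  cluster_id <- vapply(seq_len(n), function(i)
    min(sites$site_id[comp == comp[i]]), character(1))
  data.frame(site_id = sites$site_id, cluster_id = cluster_id,
             stringsAsFactors = FALSE)
}
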