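#' Construct a membrane trace
#'
#' Ordered polyline chains (nm) tracing continuous membrane in one tomogram
#' region, with the region's area for density calculations.
#'
#' @param chains list of n x 2 vertex matrices (nm), each with >= 2
#'   vertices.
#' @param area_um2 traced region area (um^2), > 0.
#' @param label region label.
#' @return object of class `membrane_trace`.
#' @export
membrane_trace <- function(chains, area_um2, label = "region") {
  chains <- lapply(chains, as.matrix)
  if (any(vapply(chains, nrow, integer(1)) < 2))
    .stop_class("each chain needs >= 2 vertices", "nedyn_input_error")
  if (area_um2 <= 0) .stop_class("region area must be > 0", "nedyn_input_error")
  structure(list(chains = chains, area_um2 = area_um2, label = label),
            class = "membrane_trace")
}

.chain_arclength <- function(chain) {
  if (nrow(chain) < 2) return(0)
  sum(sqrt(rowSums(diff(chain)^2)))
}

# closed chain: first vertex coincides with last
.chain_is_closed <- function(chain) {
  nrow(chain) > 2 && all(chain[1, ] == chain[nrow(chain), ])
}

# perpendicular spread (nm) of the terminal k vertices about the flank
# approach direction; small spread = the edge tapers rather than ending
# bluntly. `end` is "first" or "last".
.end_taper <- function(chain, end, k = 5) {
  if (end == "first") chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
  n <- nrow(chain)
  k <- min(k, n - 1)
  tip <- chain[(n - k + 1):n, , drop = FALSE]
  ref_i <- max(1, n - 2 * k)
  dir <- chain[n - k, ] - chain[ref_i, ]
  if (all(dir == 0)) dir <- chain[2, ] - chain[1, ]
  dir <- dir / sqrt(sum(dir^2))
  rel <- sweep(tip, 2, chain[n - k, ])
  max(abs(rel[, 1] * dir[2] - rel[, 2] * dir[1]))
}

#' Enumerate gap candidates between facing chain ends
#'
#' Every pair of endpoints of distinct chains that lie within
#' `pairing_max_nm` of each other and are mutually nearest becomes one
#' candidate; its width is the endpoint-to-endpoint distance, its flank
#' lengths the arc lengths of the two chains, and its taper measure the
#' terminal perpendicular spread per side. Closed chains contribute no
#' endpoints. Endpoints left unpaired (large ruptures or field edges) are
#' reported in the `unpaired` attribute.
#'
#' @param trace a [membrane_trace()].
#' @param pairing_max_nm maximum endpoint separation to pair (nm).
#' @param taper_k terminal vertices used for the taper measure.
#' @return list of `gap_candidate` objects (possibly empty), each a list
#'   with `width_nm`, `taper_nm` (length 2), `flank_nm` (length 2),
#'   `chains` (indices), `ends`.
#' @export
detect_gaps <- function(trace, pairing_max_nm = 300, taper_k = 5) {
  stopifnot(inherits(trace, "membrane_trace"))
  open_idx <- which(!vapply(trace$chains, .chain_is_closed, logical(1)))
  if (!length(open_idx)) return(structure(list(), unpaired = integer(0)))
  ends <- do.call(rbind, lapply(open_idx, function(i) {
    ch <- trace$chains[[i]]
    rbind(c(i, 1, ch[1, ]), c(i, 2, ch[nrow(ch), ]))
  }))
  m <- nrow(ends)
  D <- as.matrix(dist(ends[, 3:4, drop = FALSE]))
  same_chain <- outer(ends[, 1], ends[, 1], `==`)
  D[same_chain | D > pairing_max_nm] <- Inf
  nearest <- apply(D, 1, function(r) if (all(is.infinite(r))) NA_integer_
                   else which.min(r))
  paired <- rep(FALSE, m)
  cands <- list()
  for (i in seq_len(m)) {
    j <- nearest[i]
    if (is.na(j) || j <= i || nearest[j] != i) next
    paired[c(i, j)] <- TRUE
    side <- function(row) {
      ci <- ends[row, 1]
      end <- if (ends[row, 2] == 1) "first" else "last"
      ch <- trace$chains[[ci]]
      list(chain = ci, end = end, flank = .chain_arclength(ch),
           taper = .end_taper(ch, end, k = taper_k))
    }
    s1 <- side(i); s2 <- side(j)
    cands[[length(cands) + 1]] <- structure(list(
      width_nm = D[i, j],
      taper_nm = c(s1$taper, s2$taper),
      flank_nm = c(s1$flank, s2$flank),
      chains = c(s1$chain, s2$chain), ends = c(s1$end, s2$end)),
      class = "gap_candidate")
  }
  structure(cands, unpaired = which(!paired))
}

#' Classify a gap candidate as a nascent NPC hole
#'
#' Applies the three acceptance criteria: (1) the gap between the two
#' membrane edges is strictly less than `width_max_nm`; (2) both edges
#' taper (terminal perpendicular spread at most `taper_max_nm` per side);
#' (3) continuous membrane of at least `flank_min_nm` arc length flanks
#' the gap on both sides. A hole is accepted only when all three hold.
#'
#' @param candidate a `gap_candidate` from [detect_gaps()].
#' @param width_max_nm criterion-1 bound (strict), default 100 nm.
#' @param flank_min_nm criterion-3 minimum flank arc length, default 100 nm.
#' @param taper_max_nm criterion-2 spread bound, default 20 nm.
#' @return object of class `hole_call`: the candidate plus logicals
#'   `c1_width`, `c2_taper`, `c3_flanks`, `accepted`.
#' @export
classify_hole <- function(candidate, width_max_nm = 100, flank_min_nm = 100,
                          taper_max_nm = 20) {
  stopifnot(inherits(candidate, "gap_candidate"))
  c1 <- candidate$width_nm < width_max_nm
  c2 <- all(candidate$taper_nm <= taper_max_nm)
  c3 <- all(candidate$flank_nm >= flank_min_nm)
  structure(c(unclass(candidate),
              list(c1_width = c1, c2_taper = c2, c3_flanks = c3,
                   accepted = c1 && c2 && c3)),
            class = "hole_call")
}

#' Per-area nascent NPC hole densities
#'
#' Counts accepted holes per region and reports the per-region densities
#' (count / area), their mean over regions, and the pooled density
#' (total count / total area).
#'
#' @param calls list of [classify_hole()] results, or a list of such lists
#'   named by region.
#' @param areas data frame with columns `label` and `area_um2` (> 0), one
#'   row per region.
#' @return object of class `density_result`: list with `per_region`
#'   (data frame `label`, `area_um2`, `n_candidates`, `n_accepted`,
#'   `density_per_um2`), `mean_density_per_um2`, `pooled_density_per_um2`.
#' @export
hole_density <- function(calls, areas) {
  if (!all(c("label", "area_um2") %in% names(areas)))
    .stop_class("areas needs columns label and area_um2", "nedyn_input_error")
  if (any(areas$area_um2 <= 0))
    .stop_class("region areas must be > 0", "nedyn_input_error")
  if (length(calls) && inherits(calls[[1]], "hole_call"))
    calls <- setNames(list(calls), areas$label[1])
  missing_area <- setdiff(names(calls), areas$label)
  if (length(missing_area))
    .stop_class(paste("regions with calls but no area:",
                      paste(missing_area, collapse = ", ")), "nedyn_input_error")
  per <- do.call(rbind, lapply(seq_len(nrow(areas)), function(i) {
    lab <- areas$label[i]
    cl <- if (lab %in% names(calls)) calls[[lab]] else list()
    n_acc <- sum(vapply(cl, function(h) isTRUE(h$accepted), logical(1)))
    data.frame(label = lab, area_um2 = areas$area_um2[i],
               n_candidates = length(cl), n_accepted = n_acc,
               density_per_um2 = n_acc / areas$area_um2[i])
  }))
  structure(list(per_region = per,
                 mean_density_per_um2 = mean(per$density_per_um2),
                 pooled_density_per_um2 = sum(per$n_accepted) / sum(per$area_um2)),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  print(x$per_region)
  cat(sprintf("mean of region densities: %.2f /um^2; pooled: %.2f /um^2\n",
              x$mean_density_per_um2, x$pooled_density_per_um2))
  invisible(x)
}
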