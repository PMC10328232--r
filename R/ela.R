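#' Parameters of the electrode labelling algorithm
#'
#' The ELA samples an expanding cylinder around each contact (or bipolar
#' pair) and scores every atlas label by its mean overlap fraction across
#' the radius schedule `r_k = k * r_max / n_radii`.
#'
#' @param r_max largest cylinder radius, mm.
#' @param n_radii number of radii in the expansion schedule.
#' @param half_length cylinder half-length along the shaft, mm. `NULL`
#'   (default) resolves per contact to half the local inter-contact
#'   spacing, or 1.0 mm for isolated contacts.
#' @param sample_spacing pitch of the cubic sampling lattice, mm; must not
#'   exceed `r_max`.
#' @param mode `"monopolar"` (one cylinder per contact) or `"bipolar"`
#'   (one per adjacent pair, centred on the pair midpoint).
#' @export
ela_params <- function(r_max = 3.0, n_radii = 6L, half_length = NULL,
                       sample_spacing = 0.5,
                       mode = c("monopolar", "bipolar")) {
  mode <- match.arg(mode)
  if (r_max <= 0) stop("r_max must be positive")
  if (n_radii < 1) stop("n_radii must be >= 1")
  if (sample_spacing <= 0 || sample_spacing > r_max)
    stop("sample_spacing must be in (0, r_max]")
  if (!is.null(half_length) && half_length <= 0)
    stop("half_length must be positive")
  structure(list(r_max = r_max, n_radii = as.integer(n_radii),
                 half_length = half_length,
                 sample_spacing = sample_spacing, mode = mode),
            class = "ela_params")
}

#' Local shaft direction at a contact
#'
#' Central difference of the neighbouring contact positions for interior
#' contacts, one-sided difference at the ends, `NULL` for single-contact
#' electrodes (the caller then switches to spherical sampling).
#'
#' @param electrode an [electrode()].
#' @param index contact index.
#' @return unit 3-vector or `NULL`.
#' @export
contact_axis <- function(electrode, index) {
  p <- electrode$positions
  n <- nrow(p)
  if (index < 1 || index > n) stop("contact index out of range")
  if (n == 1) return(NULL)
  a <- max(1, index - 1)
  b <- min(n, index + 1)
  d <- p[b, ] - p[a, ]
  L <- sqrt(sum(d^2))
  if (L < 1e-12) stop("coincident neighbour contacts at index ", index)
  d / L
}

#' ELA probabilities for one sampling site
#'
#' Lays a fixed cubic lattice (pitch `sample_spacing`) over the cylinder of
#' radius `r_max` and half-length `half_length` about `position` along
#' `axis` (a sphere of radius `r_max` when `axis` is `NULL`). For each
#' radius in the schedule, the fraction of lattice points carrying each
#' parcellation label is recorded; the label probability is the mean
#' fraction across radii. Background (label 0) mass is retained, so the
#' probabilities always sum to 1 and remain comparable across contacts.
#'
#' @param position 3-vector, world mm.
#' @param axis unit 3-vector (cylinder axis) or `NULL` for spherical
#'   sampling.
#' @param parcellation label [volume_image()].
#' @param labels a [label_table()] (used for validation downstream).
#' @param params an [ela_params()].
#' @param half_length overrides `params$half_length`; defaults to 1.0 when
#'   both are `NULL`.
#' @return named numeric vector, label id -> probability (nonzero entries
#'   only), summing to 1.
#' @export
ela_probabilities <- function(position, axis, parcellation, labels,
                              params = ela_params(), half_length = NULL) {
  if (parcellation$kind != "label") stop("'parcellation' must be a label volume")
  hl <- half_length %||% params$half_length %||% 1.0
  sp <- params$sample_spacing
  # half-offset lattice, symmetric about the contact: no sample sits exactly
  # on the contact or on a lattice-aligned plane through it, which keeps
  # boundary-straddling contacts unbiased
  m <- ceiling(max(params$r_max, if (is.null(axis)) 0 else hl) / sp + 0.5)
  o1 <- (seq(-m, m - 1) + 0.5) * sp
  k <- length(o1)
  off <- cbind(rep(o1, times = k * k),
               rep(rep(o1, each = k), times = k),
               rep(o1, each = k * k))
  if (is.null(axis)) {
    radial <- sqrt(rowSums(off^2))
    keep <- rep(TRUE, nrow(off))
  } else {
    axis <- axis / sqrt(sum(axis^2))
    ax <- as.numeric(off %*% axis)
    radial <- sqrt(pmax(rowSums(off^2) - ax^2, 0))
    keep <- abs(ax) <= hl + 1e-12
  }
  off <- off[keep, , drop = FALSE]
  radial <- radial[keep]
  radii <- seq_len(params$n_radii) * params$r_max / params$n_radii
  if (!any(radial <= radii[1]))
    stop("no lattice point inside the smallest radius; ",
         "decrease sample_spacing")
  pts <- sweep(off, 2, as.numeric(position), "+")
  labs <- sample_label(parcellation, pts)
  ids <- sort(unique(labs))
  fi <- match(labs, ids)
  P <- numeric(length(ids))
  for (r in radii) {
    sel <- radial <= r + 1e-12
    P <- P + tabulate(fi[sel], length(ids)) / sum(sel)
  }
  P <- P / length(radii)
  stats::setNames(P, ids)[P > 0]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ELA probabilities for a bipolar pair
#'
#' Identical to [ela_probabilities()] with the sampling site at the pair
#' midpoint, the axis along the pair, and half-length equal to half the
#' pair separation.
#'
#' @param electrode an [electrode()].
#' @param pair_index index `i` of the adjacent pair `(i, i+1)`.
#' @inheritParams ela_probabilities
#' @export
bipolar_probabilities <- function(electrode, pair_index, parcellation,
                                  labels, params = ela_params()) {
  n <- n_contacts(electrode)
  if (pair_index < 1 || pair_index > n - 1)
    stop("pair_index must name an adjacent pair (1..n-1)")
  a <- electrode$positions[pair_index, ]
  b <- electrode$positions[pair_index + 1, ]
  d <- b - a
  L <- sqrt(sum(d^2))
  if (L < 1e-12) stop("coincident contacts in bipolar pair ", pair_index)
  ela_probabilities((a + b) / 2, d / L, parcellation, labels, params,
                    half_length = L / 2)
}

#' Grey-matter argmax region assignment
#'
#' Assigns the label with the highest probability among cortical or
#' subcortical grey labels. Exact ties break to the lower label id and are
#' flagged. If every grey probability is zero the overall argmax is
#' returned with the fallback flag set, so white-matter or outside-brain
#' contacts are reported as such rather than silently forced into grey.
#'
#' @param probs named probability vector from [ela_probabilities()].
#' @param labels a [label_table()].
#' @return list with `label`, `probability`, `fallback`, `tie`.
#' @export
assign_region <- function(probs, labels) {
  if (length(probs) == 0) stop("empty probability vector")
  ids <- as.integer(names(probs))
  cat_ <- label_category(labels, ids)
  if (anyNA(cat_))
    stop("label id ", ids[is.na(cat_)][1], " missing from label table")
  grey <- cat_ %in% c("cortical_grey", "subcortical_grey") & probs > 0
  pool <- if (any(grey)) which(grey) else seq_along(probs)
  pmax_ <- max(probs[pool])
  cand <- pool[probs[pool] >= pmax_ - 1e-12]
  win <- cand[which.min(ids[cand])]
  list(label = ids[win], probability = as.numeric(probs[win]),
       fallback = !any(grey), tie = length(cand) > 1)
}

#' Run the ELA over a set of electrodes
#'
#' Monopolar mode produces one row per contact with the cylinder axis from
#' [contact_axis()]; bipolar mode one row per adjacent pair via
#' [bipolar_probabilities()]. Unless fixed in `params`, the cylinder
#' half-length is half the local inter-contact spacing (1.0 mm for
#' single-contact electrodes).
#'
#' @param electrodes an [electrode()] or list of them.
#' @param parcellation label [volume_image()].
#' @param labels a [label_table()].
#' @param params an [ela_params()].
#' @return object of class `label_probabilities`: probability matrix
#'   `prob` (rows = contacts/pairs, columns = label ids), `electrode` /
#'   `contact` identifiers, `label_names`, and the `assigned` data frame
#'   (label, name, probability, fallback, tie, multi_region).
#' @export
ela_label_contacts <- function(electrodes, parcellation, labels,
                               params = ela_params()) {
  electrodes <- as_electrode_list(electrodes)
  rows <- list()
  for (el in electrodes) {
    n <- n_contacts(el)
    gaps <- if (n > 1) sqrt(rowSums((el$positions[-1, , drop = FALSE] -
                                     el$positions[-n, , drop = FALSE])^2))
            else numeric(0)
    if (params$mode == "monopolar") {
      for (i in seq_len(n)) {
        hl <- params$half_length %||% (if (n == 1) 1.0 else {
          adj <- gaps[c(max(i - 1, 1), min(i, n - 1))]
          mean(adj) / 2
        })
        p <- ela_probabilities(el$positions[i, ], contact_axis(el, i),
                               parcellation, labels, params,
                               half_length = hl)
        rows[[length(rows) + 1L]] <-
          list(electrode = el$name, contact = el$contacts[i], probs = p)
      }
    } else {
      if (n < 2) next
      for (i in seq_len(n - 1)) {
        p <- bipolar_probabilities(el, i, parcellation, labels, params)
        rows[[length(rows) + 1L]] <-
          list(electrode = el$name,
               contact = paste0(el$contacts[i], "-", el$contacts[i + 1]),
               probs = p)
      }
    }
  }
  if (length(rows) == 0) stop("no contacts to label")
  all_ids <- sort(unique(unlist(lapply(rows, function(r)
    as.integer(names(r$probs))))))
  P <- matrix(0, length(rows), length(all_ids),
              dimnames = list(NULL, as.character(all_ids)))
  for (i in seq_along(rows))
    P[i, names(rows[[i]]$probs)] <- rows[[i]]$probs
  assigned <- do.call(rbind, lapply(rows, function(r) {
    a <- assign_region(r$probs, labels)
    data.frame(label = a$label, name = label_name(labels, a$label),
               probability = a$probability, fallback = a$fallback,
               tie = a$tie)
  }))
  assigned$multi_region <- rowSums(P > 0) >= 2
  structure(list(prob = P,
                 electrode = vapply(rows, `[[`, "", "electrode"),
                 contact = vapply(rows, `[[`, "", "contact"),
                 label_names = label_name(labels, all_ids),
                 assigned = assigned),
            class = "label_probabilities")
}

#' @export
print.label_probabilities <- function(x, ...) {
  cat(sprintf("<label_probabilities> %d contacts x %d labels\n",
              nrow(x$prob), ncol(x$prob)))
  invisible(x)
}
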