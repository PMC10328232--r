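#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param frame frame tag to attach, see [volume_image()].
#' @param kind `"label"`, `"intensity"` or `NULL` to guess.
#' @return a [volume_image()].
#' @export
read_volume <- function(path, frame = "scanner_ras", kind = NULL) {
  force(path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI volume '",
                                           path, "': ", conditionMessage(e)))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- as.array(img)
  grid <- if (all(grid == round(grid)) && max(abs(grid)) < .Machine$integer.max)
    array(as.integer(grid), dim = dim(grid))
  else array(as.numeric(grid), dim = dim(grid))
  volume_image(grid, aff, frame = frame, kind = kind)
}

#' Write a volume as NIfTI-1
#' @param vol a [volume_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# FreeSurfer surface-RAS offset: world position of the volume's center voxel
surface_center_offset <- function(vol) {
  d <- dim(vol$grid)
  as.numeric(voxel_to_world(d / 2, vol))
}

FS_TRIANGLE_MAGIC <- c(255L, 255L, 254L)

#' Read a FreeSurfer binary triangle surface
#'
#' FreeSurfer stores surface meshes in its own surface-RAS frame, which is
#' offset from scanner RAS by the world position of the volume center. When
#' the companion volume is supplied the offset is applied so the mesh lands
#' in the same scanner-RAS frame as the picks and the parcellation;
#' otherwise the mesh is tagged `surface_ras` so mixing is detectable.
#'
#' @param path path to the surface file.
#' @param volume optional companion [volume_image()] used to convert
#'   surface RAS to scanner RAS.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, volume = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  if (length(magic) < 3 || !all(magic == FS_TRIANGLE_MAGIC))
    stop("'", path, "' is not a FreeSurfer triangle surface (bad magic number)")
  # creator string: terminated by "\n\n"
  prev <- 0L
  repeat {
    ch <- readBin(con, "integer", 1, size = 1, signed = FALSE)
    if (length(ch) == 0) stop("'", path, "' is truncated")
    if (ch == 10L && prev == 10L) break
    prev <- ch
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  v <- readBin(con, "numeric", 3 * nv, size = 4, endian = "big")
  f <- readBin(con, "integer", 3 * nf, size = 4, endian = "big")
  if (length(v) < 3 * nv || length(f) < 3 * nf)
    stop("'", path, "' is truncated")
  vertices <- matrix(v, ncol = 3, byrow = TRUE)
  faces <- matrix(f, ncol = 3, byrow = TRUE) + 1L
  frame <- "surface_ras"
  if (!is.null(volume)) {
    vertices <- sweep(vertices, 2, surface_center_offset(volume), "+")
    frame <- volume$frame
  }
  surface_mesh(vertices, faces, frame = frame)
}

#' Write a FreeSurfer binary triangle surface
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param volume optional companion volume; if given, vertices are written
#'   in FreeSurfer surface RAS (scanner RAS minus the center offset).
#' @export
write_surface <- function(mesh, path, volume = NULL) {
  v <- mesh$vertices
  if (!is.null(volume)) v <- sweep(v, 2, surface_center_offset(volume), "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(FS_TRIANGLE_MAGIC), con, size = 1)
  writeBin(charToRaw("created by ieegloc\n\n"), con)
  writeBin(c(nrow(v), nrow(mesh$faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(v)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4, endian = "big")
  invisible(path)
}

LABEL_CATEGORIES <- c("cortical_grey", "subcortical_grey", "white", "csf",
                      "background")

#' Label lookup table
#'
#' @param id non-negative integer label ids (unique; 0 = background must be
#'   present).
#' @param name region names.
#' @param category one of `"cortical_grey"`, `"subcortical_grey"`,
#'   `"white"`, `"csf"`, `"background"` per label.
#' @param color n x 3 RGB matrix (0-255).
#' @return a `label_table` data frame.
#' @export
label_table <- function(id, name, category, color = NULL) {
  id <- as.integer(id)
  if (anyDuplicated(id)) stop("duplicate label id ", id[duplicated(id)][1])
  if (any(id < 0)) stop("label ids must be non-negative")
  if (!0L %in% id) stop("label id 0 (background) must be present")
  if (!all(category %in% LABEL_CATEGORIES))
    stop("invalid category: ", setdiff(category, LABEL_CATEGORIES)[1])
  if (any(category[id == 0] != "background"))
    stop("label id 0 must have category 'background'")
  if (is.null(color)) color <- matrix(0L, length(id), 3)
  tab <- data.frame(id = id, name = as.character(name),
                    category = as.character(category),
                    R = color[, 1], G = color[, 2], B = color[, 3])
  class(tab) <- c("label_table", "data.frame")
  tab
}

# default category from canonical FreeSurfer aseg / DKT names, falling back
# to documented id-range rules: 0 background; 1-99 and 1000-2999 cortical
# grey; 100-199 and 3000-5999 white; 200-999 subcortical grey; else
# background.
default_label_category <- function(id, name) {
  n <- tolower(name)
  if (id == 0L || grepl("unknown", n)) return("background")
  if (grepl("white-matter|^wm-|white_matter", n)) return("white")
  if (grepl("ventricle|csf|choroid|vessel", n)) return("csf")
  if (grepl(paste0("hippocampus|amygdala|thalamus|caudate|putamen|pallidum|",
                   "accumbens|ventraldc|brain-stem|brainstem|cerebellum"), n))
    return("subcortical_grey")
  if (grepl("^ctx|cortex", n)) return("cortical_grey")
  if (id < 100L) return("cortical_grey")
  if (id < 200L) return("white")
  if (id < 1000L) return("subcortical_grey")
  if (id < 3000L) return("cortical_grey")
  if (id < 6000L) return("white")
  "background"
}

#' Read a FreeSurfer-style color lookup table
#'
#' Parses the whitespace-delimited `id name R G B A` dialect (`#` comments).
#' Categories are taken from `category_map` when the name is listed there,
#' otherwise from built-in rules for canonical aseg/DKT names, otherwise
#' from id-range rules (see [label_table()] docs). Background id 0 is added
#' if the file lacks it.
#'
#' @param path LUT file path.
#' @param category_map optional named character vector, `name -> category`.
#' @return a [label_table()].
#' @export
read_label_table <- function(path, category_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("'", path, "' contains no label entries")
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) < 5L)
  if (length(bad))
    stop("malformed LUT line ", bad[1], " in '", path, "'")
  id <- as.integer(vapply(parts, `[[`, "", 1))
  if (anyNA(id)) stop("non-integer label id in '", path, "'")
  if (anyDuplicated(id)) stop("duplicate label id ", id[duplicated(id)][1])
  name <- vapply(parts, `[[`, "", 2)
  col <- t(vapply(parts, function(p) as.integer(p[3:5]), integer(3)))
  if (!0L %in% id) {
    id <- c(0L, id); name <- c("Unknown", name); col <- rbind(c(0L, 0L, 0L), col)
  }
  category <- vapply(seq_along(id), function(i) {
    if (!is.null(category_map) && name[i] %in% names(category_map))
      as.character(category_map[[name[i]]])
    else default_label_category(id[i], name[i])
  }, "")
  label_table(id, name, category, col)
}

#' Write a label table in FreeSurfer color-LUT dialect
#' @param labels a [label_table()].
#' @param path output path.
#' @export
write_label_table <- function(labels, path) {
  lines <- c("# id name R G B A",
             sprintf("%d %s %d %d %d 0", labels$id, labels$name,
                     labels$R, labels$G, labels$B))
  writeLines(lines, path)
  invisible(path)
}

label_category <- function(labels, ids) {
  labels$category[match(ids, labels$id)]
}

label_name <- function(labels, ids) {
  labels$name[match(ids, labels$id)]
}

#' Read manually picked contact coordinates
#'
#' Accepts comma- or tab-delimited text with a header naming (at least)
#' `electrode`, `contact`, `x`, `y`, `z` columns (case-insensitive; an
#' optional `size` column carries contact size in mm). Contacts are grouped
#' by electrode preserving file order within each electrode.
#'
#' @param path pick file path.
#' @param kinds optional named character vector `electrode -> kind`
#'   (default `"depth"`).
#' @param grid_shapes optional named list `electrode -> c(rows, cols)`.
#' @return named list of [electrode()] objects in first-appearance order.
#' @export
read_contacts <- function(path, kinds = NULL, grid_shapes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("'", path, "' has no contact rows")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  hdr <- tolower(trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]]))
  need <- c("electrode", "contact", "x", "y", "z")
  if (!all(need %in% hdr))
    stop("'", path, "' header must name columns: ",
         paste(need, collapse = ", "))
  ci <- match(need, hdr)
  si <- match("size", hdr)
  rows <- lapply(seq_along(lines)[-1], function(ln) {
    f <- trimws(strsplit(lines[ln], sep, fixed = TRUE)[[1]])
    xyz <- suppressWarnings(as.numeric(f[ci[3:5]]))
    if (anyNA(xyz) || !all(is.finite(xyz)))
      stop("non-numeric coordinate at line ", ln, " of '", path, "'")
    sz <- if (!is.na(si) && length(f) >= si && nzchar(f[si]) && f[si] != "n/a")
      suppressWarnings(as.numeric(f[si])) else NA_real_
    list(electrode = f[ci[1]], contact = f[ci[2]], xyz = xyz, size = sz)
  })
  enames <- vapply(rows, `[[`, "", "electrode")
  out <- list()
  for (e in unique(enames)) {
    sel <- rows[enames == e]
    pos <- do.call(rbind, lapply(sel, `[[`, "xyz"))
    kind <- if (!is.null(kinds) && e %in% names(kinds)) kinds[[e]] else "depth"
    shape <- if (!is.null(grid_shapes)) grid_shapes[[e]] else NULL
    out[[e]] <- electrode(e, pos, vapply(sel, `[[`, "", "contact"),
                          kind = kind, grid_shape = shape,
                          size = vapply(sel, `[[`, 0, "size"))
  }
  out
}

#' Write contact coordinates as delimited text
#' @param electrodes an [electrode()] or list of them.
#' @param path output path.
#' @param sep `","` or `"\t"`.
#' @export
write_contacts <- function(electrodes, path, sep = ",") {
  electrodes <- as_electrode_list(electrodes)
  lines <- paste(c("electrode", "contact", "x", "y", "z", "size"),
                 collapse = sep)
  for (el in electrodes) {
    sz <- ifelse(is.na(el$size), "", formatC(el$size, digits = 9, format = "g"))
    lines <- c(lines, paste(el$name, el$contacts,
                            formatC(el$positions[, 1], digits = 9, format = "g"),
                            formatC(el$positions[, 2], digits = 9, format = "g"),
                            formatC(el$positions[, 3], digits = 9, format = "g"),
                            sz, sep = sep))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a mesh as binary STL
#' @param mesh a [surface_mesh()] with at least one face.
#' @param path output path.
#' @export
write_stl <- function(mesh, path) {
  if (nrow(mesh$faces) == 0) stop("cannot write an empty mesh to STL")
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("ieegloc binary STL", width = -80))
  writeBin(header[1:80], con)
  writeBin(nrow(mesh$faces), con, size = 4, endian = "little")
  fn <- face_normals(mesh)$normals
  v <- mesh$vertices; f <- mesh$faces
  # 12 floats per triangle: normal, v1, v2, v3
  tri <- cbind(fn, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  for (i in seq_len(nrow(tri))) {
    writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL into a mesh
#'
#' Vertices identical to 1e-4 mm are merged so that watertight connectivity
#' written by [write_stl()] is recovered.
#'
#' @param path STL file path.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(nt) == 0 || nt <= 0) stop("'", path, "' is not a valid binary STL")
  verts <- matrix(NA_real_, 3 * nt, 3)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) stop("'", path, "' is truncated")
    verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "integer", 1, size = 2, endian = "little")
  }
  key <- paste(round(verts[, 1], 4), round(verts[, 2], 4), round(verts[, 3], 4))
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(uverts, faces, check_watertight = FALSE)
}

#' Write the per-contact region-probability spreadsheet
#'
#' One row per contact (or bipolar pair), one `p_<id>_<name>` column per
#' label with nonzero probability anywhere, plus the assigned region and its
#' (maximum grey-matter) probability. Values carry 9 significant digits so
#' probability sums survive a round-trip within 1e-6.
#'
#' @param probs a `label_probabilities` object from [ela_label_contacts()].
#' @param path output CSV path.
#' @export
write_probability_table <- function(probs, path) {
  if (!inherits(probs, "label_probabilities") || nrow(probs$prob) == 0)
    stop("'probs' must be a non-empty label_probabilities object")
  P <- probs$prob
  pcols <- apply(P, 2, function(col)
    formatC(col, digits = 9, format = "g"))
  if (is.null(dim(pcols))) pcols <- matrix(pcols, nrow = 1)
  colnames(pcols) <- paste0("p_", colnames(P), "_",
                            gsub("[^A-Za-z0-9_-]", "_", probs$label_names))
  df <- data.frame(electrode = probs$electrode, contact = probs$contact,
                   assigned_label = probs$assigned$label,
                   assigned_name = probs$assigned$name,
                   assigned_probability = formatC(probs$assigned$probability,
                                                  digits = 9, format = "g"),
                   fallback = probs$assigned$fallback,
                   multi_region = probs$assigned$multi_region,
                   pcols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a probability spreadsheet written by [write_probability_table()]
#' @param path CSV path.
#' @return data frame with numeric `p_*` columns.
#' @export
read_probability_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Export electrode localizations in iEEG-BIDS layout
#'
#' Writes `<prefix>_electrodes.tsv` (tab-delimited, `n/a` for missing
#' values) with the required `name x y z size` columns plus `group` (the
#' electrode), `tissue` and `label`/`label_name` columns from the tissue
#' classification, and optional distance/angle measurement columns; and
#' `<prefix>_coordsystem.json` declaring the coordinate frame with units
#' mm.
#'
#' @param electrodes an [electrode()] or list of them.
#' @param classifications optional `tissue_classification` data frame from
#'   [classify_contacts()]; contacts without one are reported as `n/a`.
#' @param measurements optional measurements data frame from
#'   [contact_measurements()] (matched on electrode + contact).
#' @param out_dir output directory (created if missing).
#' @param coordinate_frame_name value for `iEEGCoordinateSystem`.
#' @param prefix BIDS filename prefix.
#' @return invisible character vector of the two file paths.
#' @export
write_bids_electrodes <- function(electrodes, classifications = NULL,
                                  measurements = NULL, out_dir,
                                  coordinate_frame_name = "Other",
                                  prefix = "sub-01") {
  electrodes <- as_electrode_list(electrodes)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (el in electrodes) {
    for (i in seq_len(n_contacts(el))) {
      key <- c(el$name, el$contacts[i])
      tissue <- lab <- labname <- "n/a"
      if (!is.null(classifications)) {
        m <- which(classifications$electrode == key[1] &
                   classifications$contact == key[2])
        if (length(m)) {
          tissue <- classifications$class[m[1]]
          lab <- as.character(classifications$label[m[1]])
          if ("label_name" %in% names(classifications))
            labname <- classifications$label_name[m[1]]
        }
      }
      meas <- c(dist_pial = NA_real_, dist_white = NA_real_,
                intercontact = NA_real_, angle_deg = NA_real_)
      if (!is.null(measurements)) {
        m <- which(measurements$electrode == key[1] &
                   measurements$contact == key[2])
        if (length(m)) {
          for (cn in names(meas))
            if (cn %in% names(measurements))
              meas[cn] <- measurements[[cn]][m[1]]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(el$name, el$contacts[i]),
        x = el$positions[i, 1], y = el$positions[i, 2], z = el$positions[i, 3],
        size = if (is.na(el$size[i])) "n/a" else
          formatC(el$size[i], digits = 9, format = "g"),
        group = el$name, tissue = tissue, label = lab, label_name = labname,
        dist_pial = fmt_or_na(meas["dist_pial"]),
        dist_white = fmt_or_na(meas["dist_white"]),
        intercontact = fmt_or_na(meas["intercontact"]),
        angle_deg = fmt_or_na(meas["angle_deg"]))
    }
  }
  tab <- do.call(rbind, rows)
  for (cn in c("x", "y", "z"))
    tab[[cn]] <- formatC(tab[[cn]], digits = 9, format = "g")
  tsv <- file.path(out_dir, paste0(prefix, "_electrodes.tsv"))
  lines <- c(paste(names(tab), collapse = "\t"),
             apply(tab, 1, paste, collapse = "\t"))
  writeLines(lines, tsv)
  js <- file.path(out_dir, paste0(prefix, "_coordsystem.json"))
  jsonlite::write_json(list(
    iEEGCoordinateSystem = coordinate_frame_name,
    iEEGCoordinateUnits = "mm",
    iEEGCoordinateSystemDescription = paste(
      "World RAS millimetres in the native space of the pre-operative",
      "T1-weighted MRI")),
    js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv, js))
}

fmt_or_na <- function(x) {
  if (is.na(x)) "n/a" else formatC(as.numeric(x), digits = 9, format = "g")
}
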