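# Data model for MSI datasets and imzML I/O.
#
# Coordinate convention (enforced in tests): imzML positions are 1-based,
# x = column, y = row; internal image arrays are row-major with
# [row = y, col = x].

#' Construct a centroided spectrum
#'
#' A spectrum is one pixel's centroided peak list: strictly increasing m/z
#' values paired with non-negative intensities, restricted to the
#' acquisition range of 50--1000 Da.
#'
#' @param mz Numeric vector of m/z values in Da, strictly increasing.
#' @param intensity Numeric vector of non-negative ion counts, same length.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `msi_spectrum`: a list with elements `mz` and
#'   `intensity`.
#' @examples
#' s <- msi_spectrum(c(756.5514, 778.5357), c(100, 40))
#' length(s$mz)
#' @export
msi_spectrum <- function(mz, intensity, validate = TRUE) {
  s <- structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
                 class = "msi_spectrum")
  if (validate) validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  if (length(s$mz) != length(s$intensity))
    stop("spectrum m/z and intensity lengths differ", call. = FALSE)
  if (anyNA(s$mz) || anyNA(s$intensity))
    stop("spectrum contains NA/NaN values", call. = FALSE)
  if (length(s$mz)) {
    if (any(diff(s$mz) <= 0))
      stop("spectrum m/z values must be strictly increasing", call. = FALSE)
    if (any(s$intensity < 0))
      stop("spectrum intensities must be non-negative", call. = FALSE)
    if (min(s$mz) < MZ_RANGE[1] || max(s$mz) > MZ_RANGE[2])
      stop(sprintf("spectrum m/z outside acquisition range [%g, %g] Da",
                   MZ_RANGE[1], MZ_RANGE[2]), call. = FALSE)
  }
  invisible(s)
}

#' @export
print.msi_spectrum <- function(x, ...) {
  cat(sprintf("<msi_spectrum> %d peaks, m/z %.4f-%.4f\n", length(x$mz),
              if (length(x$mz)) min(x$mz) else NA, if (length(x$mz)) max(x$mz) else NA))
  invisible(x)
}

#' Construct a tissue-section MSI dataset
#'
#' A section is a pixel grid of centroided spectra together with the study
#' metadata that the imzML standard has no slot for (carried instead in the
#' sidecar manifest): subject, time point, treatment and acquisition order.
#'
#' @param spectra List of [msi_spectrum] objects, one per pixel, parallel to
#'   the rows of `coords`.
#' @param coords Data frame with integer columns `x` (column index) and `y`
#'   (row index), both 1-based.
#' @param grid_shape Integer vector `c(n_rows, n_cols)`.
#' @param section_id Section identifier string.
#' @param pixel_size_um Pixel edge length in micrometres (default 35, the
#'   acquisition pixel size).
#' @param subject_id Biological replicate identifier (`NA` for blanks).
#' @param time_point_h Sampling time in hours after the sixth brood, one of
#'   8, 24, 48, 72 (`NA` for blanks).
#' @param treatment `"control"` or `"BPA"` (`NA` for blanks).
#' @param acquisition_index Non-negative integer position in the acquisition
#'   order.
#' @param is_blank Logical; `TRUE` for blank DESI slides.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `msi_section`.
#' @export
msi_section <- function(spectra, coords, grid_shape, section_id,
                        pixel_size_um = 35, subject_id = NA_character_,
                        time_point_h = NA_real_, treatment = NA_character_,
                        acquisition_index = 0L, is_blank = FALSE,
                        validate = TRUE) {
  sec <- structure(list(
    section_id = as.character(section_id),
    spectra = spectra,
    coords = data.frame(x = as.integer(coords$x), y = as.integer(coords$y)),
    grid_shape = as.integer(grid_shape),
    pixel_size_um = pixel_size_um,
    subject_id = as.character(subject_id),
    time_point_h = as.numeric(time_point_h),
    treatment = as.character(treatment),
    acquisition_index = as.integer(acquisition_index),
    is_blank = isTRUE(is_blank)
  ), class = "msi_section")
  if (validate) validate_section(sec)
  sec
}

validate_section <- function(sec) {
  if (length(sec$spectra) != nrow(sec$coords))
    stop("number of spectra does not match number of pixel coordinates",
         call. = FALSE)
  if (length(sec$spectra) == 0L)
    stop("section has no pixels", call. = FALSE)
  if (sec$pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  bad <- sec$coords$x < 1L | sec$coords$y < 1L |
    sec$coords$x > sec$grid_shape[2] | sec$coords$y > sec$grid_shape[1]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("pixel (x=%d, y=%d) lies outside the declared %dx%d grid",
                 sec$coords$x[i], sec$coords$y[i],
                 sec$grid_shape[1], sec$grid_shape[2]), call. = FALSE)
  }
  if (anyDuplicated(sec$coords))
    stop("duplicated pixel coordinates in section", call. = FALSE)
  # Study metadata lives in the sidecar manifest, so it may be absent on a
  # bare read; when present it must be valid, and blanks must not carry it.
  if (sec$is_blank) {
    if (!is.na(sec$time_point_h) || !is.na(sec$treatment))
      stop("blank slides must not carry time point or treatment metadata",
           call. = FALSE)
  } else {
    if (!is.na(sec$time_point_h) && !sec$time_point_h %in% c(8, 24, 48, 72))
      stop("time_point_h must be one of 8, 24, 48, 72", call. = FALSE)
    if (!is.na(sec$treatment) && !sec$treatment %in% c("control", "BPA"))
      stop("treatment must be 'control' or 'BPA'", call. = FALSE)
  }
  invisible(sec)
}

#' @export
print.msi_section <- function(x, ...) {
  cat(sprintf("<msi_section> %s: %d pixels on a %dx%d grid (%g um/pixel)%s\n",
              x$section_id, length(x$spectra), x$grid_shape[1], x$grid_shape[2],
              x$pixel_size_um,
              if (x$is_blank) " [blank]"
              else sprintf(" [%s, %g h]", x$treatment, x$time_point_h)))
  invisible(x)
}

#' Construct a pixels-by-features matrix
#'
#' Consensus m/z features across pixels with explicit missingness: a peak
#' absent from a pixel is `NA`, never 0, and every observed value is > 0.
#'
#' @param feature_mz Strictly increasing numeric vector of consensus feature
#'   m/z centroids (Da).
#' @param values Numeric matrix, pixels x features, `NA` marking missing.
#' @param pixel_meta Data frame with one row per pixel: `section_id`, `x`,
#'   `y`, and optionally `region_label`, `time_point_h`, `treatment`.
#' @param grid_shapes Named list mapping section_id to `c(n_rows, n_cols)`.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(feature_mz, values, pixel_meta,
                           grid_shapes = list(), validate = TRUE) {
  if (!("region_label" %in% names(pixel_meta)))
    pixel_meta$region_label <- NA_character_
  fm <- structure(list(
    feature_mz = as.numeric(feature_mz),
    values = values,
    pixel_meta = pixel_meta,
    grid_shapes = grid_shapes
  ), class = "feature_matrix")
  if (validate) validate_feature_matrix(fm)
  fm
}

validate_feature_matrix <- function(fm) {
  if (ncol(fm$values) != length(fm$feature_mz))
    stop("values column count does not match feature_mz length", call. = FALSE)
  if (nrow(fm$values) != nrow(fm$pixel_meta))
    stop("values row count does not match pixel_meta", call. = FALSE)
  if (length(fm$feature_mz) > 1 && any(diff(fm$feature_mz) <= 0))
    stop("feature_mz must be strictly increasing", call. = FALSE)
  obs <- fm$values[!is.na(fm$values)]
  if (length(obs) && any(obs <= 0))
    stop("observed feature-matrix values must be > 0 (absence is NA, not 0)",
         call. = FALSE)
  invisible(fm)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d pixels x %d features (%d sections, %.1f%% observed)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$pixel_meta$section_id)),
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Subset a feature matrix by pixel rows and/or feature columns.
subset_fm <- function(fm, pixels = NULL, features = NULL) {
  if (!is.null(features)) {
    fm$values <- fm$values[, features, drop = FALSE]
    fm$feature_mz <- fm$feature_mz[features]
  }
  if (!is.null(pixels)) {
    fm$values <- fm$values[pixels, , drop = FALSE]
    fm$pixel_meta <- fm$pixel_meta[pixels, , drop = FALSE]
    rownames(fm$pixel_meta) <- NULL
  }
  fm
}

## ---- imzML writing -------------------------------------------------------

# Deterministic 16-byte identifier derived from the section id and pixel
# count, so that writing the same section twice yields identical files.
imzml_uuid <- function(section_id, n) {
  b <- as.integer(charToRaw(paste0(section_id, ":", n)))
  h <- (seq_len(16) * 37L) %% 256L
  for (i in seq_along(b)) {
    j <- (i - 1L) %% 16L + 1L
    h[j] <- (h[j] * 31L + b[i]) %% 256L
  }
  as.raw(h)
}

format_uuid <- function(raw16) {
  hx <- paste(sprintf("%02x", as.integer(raw16)), collapse = "")
  sprintf("{%s-%s-%s-%s-%s}", substr(hx, 1, 8), substr(hx, 9, 12),
          substr(hx, 13, 16), substr(hx, 17, 20), substr(hx, 21, 32))
}

ibd_path <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

#' Write a section as processed-mode imzML
#'
#' Emits an imzML 1.1 XML file plus its `.ibd` binary companion with
#' per-pixel m/z (64-bit float) and intensity (32-bit float) arrays,
#' readable by [read_imzml()] and by third-party imzML readers.
#'
#' @param section An [msi_section].
#' @param path Output path ending in `.imzML`; the binary companion is
#'   written alongside with extension `.ibd`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(section, path) {
  validate_section(section)
  n <- length(section$spectra)
  uuid <- imzml_uuid(section$section_id, n)

  con <- file(ibd_path(path), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  mz_off <- mz_len <- int_off <- int_len <- integer(n)
  for (i in seq_len(n)) {
    sp <- section$spectra[[i]]
    k <- length(sp$mz)
    mz_off[i] <- offset; mz_len[i] <- k
    if (k) writeBin(as.numeric(sp$mz), con, size = 8, endian = "little")
    offset <- offset + 8 * k
    int_off[i] <- offset; int_len[i] <- k
    if (k) writeBin(as.numeric(sp$intensity), con, size = 4, endian = "little")
    offset <- offset + 4 * k
  }

  cv <- function(ref, acc, name, value = NULL, unit = NULL) {
    v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
    u <- if (is.null(unit)) "" else unit
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s%s/>', ref, acc, name, v, u)
  }
  head_xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<cvList count="3">\n',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>\n',
    '</cvList>\n',
    '<fileDescription><fileContent>\n',
    cv("IMS", "IMS:1000031", "processed"), "\n",
    cv("IMS", "IMS:1000080", "universally unique identifier", format_uuid(uuid)), "\n",
    cv("MS", "MS:1000127", "centroid spectrum"), "\n",
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">\n',
    '<referenceableParamGroup id="mzArray">\n',
    cv("MS", "MS:1000514", "m/z array", NULL,
       ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"'), "\n",
    cv("MS", "MS:1000523", "64-bit float"), "\n",
    cv("MS", "MS:1000576", "no compression"), "\n",
    cv("IMS", "IMS:1000101", "external data", "true"), "\n",
    '</referenceableParamGroup>\n',
    '<referenceableParamGroup id="intensityArray">\n',
    cv("MS", "MS:1000515", "intensity array", NULL,
       ' unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"'), "\n",
    cv("MS", "MS:1000521", "32-bit float"), "\n",
    cv("MS", "MS:1000576", "no compression"), "\n",
    cv("IMS", "IMS:1000101", "external data", "true"), "\n",
    '</referenceableParamGroup>\n',
    '</referenceableParamGroupList>\n',
    '<softwareList count="1"><software id="daphmsi" version="0.1.0"/></softwareList>\n',
    '<scanSettingsList count="1"><scanSettings id="scansettings1">\n',
    cv("IMS", "IMS:1000042", "max count of pixels x", section$grid_shape[2]), "\n",
    cv("IMS", "IMS:1000043", "max count of pixels y", section$grid_shape[1]), "\n",
    cv("IMS", "IMS:1000046", "pixel size (x)", section$pixel_size_um), "\n",
    cv("IMS", "IMS:1000047", "pixel size y", section$pixel_size_um), "\n",
    '</scanSettings></scanSettingsList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="daphmsi">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC1">\n', section$section_id),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="export">\n', n))

  spec_xml <- sprintf(paste0(
    '<spectrum id="spectrum=%d" index="%d" defaultArrayLength="0">',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
    '<scanList count="1">',
    '<cvParam cvRef="MS" accession="MS:1000795" name="no combination"/>',
    '<scan instrumentConfigurationRef="IC1">',
    '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
    '</scan></scanList>',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="mzArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
    '<binary/></binaryDataArray>',
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="intensityArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
    '<binary/></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    seq_len(n), seq_len(n) - 1L,
    section$coords$x, section$coords$y,
    mz_len, 8L * mz_len, mz_off,
    int_len, 4L * int_len, int_off)

  writeLines(c(head_xml, spec_xml, "</spectrumList>\n</run>\n</mzML>"),
             path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## ---- imzML reading -------------------------------------------------------

xml_cv_values <- function(doc, accession) {
  xml2::xml_attr(
    xml2::xml_find_all(doc, sprintf(".//d1:cvParam[@accession='%s']", accession)),
    "value")
}

#' Read an imzML file into a section
#'
#' Supports processed-mode (per-pixel m/z arrays) and continuous-mode
#' imzML with uncompressed external binary data. Profile-mode data are
#' rejected unless `centroided = TRUE` asserts that the stored peaks are
#' centroids: every downstream rule (SNR filtering, ppm alignment) is
#' peak-based. Study metadata is not read from imzML (which has no slot
#' for it) but from the sidecar manifest; see [read_manifest()].
#'
#' @param path Path to the `.imzML` file; the `.ibd` companion must sit
#'   alongside it.
#' @param centroided Accept files not flagged as centroided (default
#'   `FALSE`).
#' @param ... Metadata fields passed to [msi_section()] (`section_id`,
#'   `time_point_h`, `treatment`, ...); `section_id` defaults to the file
#'   name.
#' @return An [msi_section].
#' @export
read_imzml <- function(path, centroided = FALSE, ...) {
  if (!file.exists(path)) stop("imzML file not found: ", path, call. = FALSE)
  ibd <- ibd_path(path)
  if (!file.exists(ibd))
    stop("binary companion (.ibd) not found for ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed imzML XML in ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  mode_processed <- length(xml2::xml_find_all(
    doc, ".//d1:cvParam[@accession='IMS:1000031']")) > 0
  profile <- length(xml2::xml_find_all(
    doc, ".//d1:fileDescription//d1:cvParam[@accession='MS:1000128']")) > 0
  if (profile && !centroided)
    stop("profile-mode imzML rejected: this workflow operates on centroided ",
         "peak lists (set centroided = TRUE to override)", call. = FALSE)

  nx <- as.integer(xml_cv_values(doc, "IMS:1000042")[1])
  ny <- as.integer(xml_cv_values(doc, "IMS:1000043")[1])
  px_size <- as.numeric(xml_cv_values(doc, "IMS:1000046")[1])
  if (is.na(px_size)) px_size <- 35

  xs <- as.integer(xml_cv_values(doc, "IMS:1000050"))
  ys <- as.integer(xml_cv_values(doc, "IMS:1000051"))
  n <- length(xs)
  if (n == 0L) stop("imzML declares no spectra: ", path, call. = FALSE)

  # Per binaryDataArray (2 per spectrum, document order): group ref,
  # external array length and offset.
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//d1:binaryDataArray/d1:referenceableParamGroupRef"),
    "ref")
  lens <- as.numeric(xml_cv_values(doc, "IMS:1000103"))
  offs <- as.numeric(xml_cv_values(doc, "IMS:1000102"))
  if (length(refs) != 2L * n || length(lens) != 2L * n || length(offs) != 2L * n)
    stop("inconsistent binary data array metadata in ", path, call. = FALSE)
  # Which referenceable group is the m/z array?
  grp <- xml2::xml_find_all(doc, ".//d1:referenceableParamGroup")
  grp_ids <- xml2::xml_attr(grp, "id")
  is_mz_grp <- vapply(grp, function(g) {
    length(xml2::xml_find_all(g, "./d1:cvParam[@accession='MS:1000514']")) > 0
  }, logical(1))
  mz_grp <- grp_ids[is_mz_grp][1]
  byte_size <- function(g) {
    if (length(xml2::xml_find_all(g, "./d1:cvParam[@accession='MS:1000523']")) > 0) 8L
    else 4L
  }
  grp_bytes <- vapply(grp, byte_size, integer(1))
  names(grp_bytes) <- grp_ids

  raw_all <- readBin(ibd, "raw", n = file.size(ibd))
  slice <- function(off, len, bytes) {
    if (len == 0) return(numeric(0))
    readBin(raw_all[(off + 1):(off + len * bytes)], "double", n = len,
            size = bytes, endian = "little")
  }

  mz_sel <- refs == mz_grp
  mz_off <- offs[mz_sel]; mz_len <- lens[mz_sel]
  int_off <- offs[!mz_sel]; int_len <- lens[!mz_sel]
  mz_bytes <- grp_bytes[[mz_grp]]
  int_bytes <- grp_bytes[[setdiff(grp_ids, mz_grp)[1]]]

  if (!mode_processed && length(unique(mz_off)) == 1L) {
    shared_mz <- slice(mz_off[1], mz_len[1], mz_bytes)
  } else shared_mz <- NULL

  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    mzv <- if (is.null(shared_mz)) slice(mz_off[i], mz_len[i], mz_bytes) else shared_mz
    iv <- slice(int_off[i], int_len[i], int_bytes)
    if (!is.null(shared_mz) && length(iv) == length(mzv)) {
      keep <- iv > 0  # continuous mode stores the full common axis
      mzv <- mzv[keep]; iv <- iv[keep]
    }
    spectra[[i]] <- msi_spectrum(mzv, iv, validate = FALSE)
  }

  meta <- list(...)
  if (is.null(meta$section_id))
    meta$section_id <- sub("\\.imzml$", "", basename(path), ignore.case = TRUE)
  bad <- which(xs > nx | ys > ny | xs < 1L | ys < 1L)
  if (length(bad))
    stop(sprintf("spectrum %d at (x=%d, y=%d) lies outside the declared %dx%d grid in %s",
                 bad[1], xs[bad[1]], ys[bad[1]], ny, nx, path), call. = FALSE)
  do.call(msi_section, c(list(
    spectra = spectra, coords = data.frame(x = xs, y = ys),
    grid_shape = c(ny, nx), pixel_size_um = px_size,
    is_blank = isTRUE(meta$is_blank)),
    meta[setdiff(names(meta), "is_blank")]))
}

## ---- study manifest ------------------------------------------------------

#' Write a study manifest
#'
#' The manifest is the sidecar config carrying the study metadata that
#' imzML cannot: one record per section with file path, subject, time
#' point, treatment, acquisition order and blank status.
#'
#' @param manifest Data frame with columns `section_id`, `file`,
#'   `subject_id`, `time_point_h`, `treatment`, `acquisition_index`,
#'   `is_blank`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- as.list(manifest[i, , drop = FALSE])
    lapply(r, function(v) if (is.factor(v)) as.character(v) else v[[1]])
  })
  yaml::write_yaml(list(sections = recs), path)
  invisible(path)
}

#' Read a study manifest
#'
#' @param path YAML manifest written by [write_manifest()].
#' @return Data frame with one row per section.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  recs <- yaml::read_yaml(path)$sections
  do.call(rbind, lapply(recs, function(r) {
    data.frame(section_id = r$section_id, file = r$file,
               subject_id = if (is.null(r$subject_id)) NA_character_ else r$subject_id,
               time_point_h = if (is.null(r$time_point_h)) NA_real_ else r$time_point_h,
               treatment = if (is.null(r$treatment)) NA_character_ else r$treatment,
               acquisition_index = r$acquisition_index,
               is_blank = isTRUE(r$is_blank))
  }))
}

#' Load every section of a study from its manifest
#'
#' @param manifest_path Path to a YAML manifest; relative `file` entries are
#'   resolved against the manifest's directory.
#' @return Named list of [msi_section] objects keyed by section_id.
#' @export
load_study <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  out <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, f)
    read_imzml(f, section_id = man$section_id[i],
               subject_id = man$subject_id[i],
               time_point_h = man$time_point_h[i],
               treatment = man$treatment[i],
               acquisition_index = man$acquisition_index[i],
               is_blank = man$is_blank[i])
  })
  names(out) <- man$section_id
  out
}
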