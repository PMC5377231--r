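# Stack and table I/O. All unit and axis conventions live here:
# arrays are (z, y, x) with z = 1 nearest the objective; spacing is
# (dz, dy, dx) in um/voxel; volumes um^3, areas um^2, diameters um.

#' Read a 3D image stack from TIFF / OME-TIFF
#'
#' Reads a single-channel multi-page TIFF into a [VoxelGrid-class]. Voxel
#' spacing is taken from OME-XML metadata (\code{PhysicalSizeX/Y/Z} on the
#' \code{Pixels} element) when present; otherwise \code{spacingOverride}
#' must be supplied. Missing spacing is a hard error, never a silent
#' default: volumes are meaningless without it.
#'
#' @param path path to a readable single-channel TIFF/OME-TIFF stack.
#' @param spacingOverride optional numeric(3) \code{c(dz, dy, dx)} in
#'   micrometres, used when the file carries no OME spacing metadata.
#' @param channel for multi-channel pages, the 1-based channel to extract;
#'   multi-channel input without a channel selector is an error.
#' @return A [VoxelGrid-class] indexed \code{(z, y, x)}, page 1 at
#'   \code{z = 1}.
#' @seealso [writeStack()]
#' @export
readStack <- function(path, spacingOverride = NULL, channel = NULL) {
    if (!file.exists(path))
        stop("cannot read stack: file not found: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
        stop("stack must have >= 2 z-planes; got ", length(pages))
    fmt <- attr(pages[[1]], "sample.format")
    if (!is.null(fmt) && fmt != "float") {
        # integer samples: re-read raw counts instead of [0, 1] normalization
        pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
        if (!is.list(pages)) pages <- list(pages)
    }
    first <- pages[[1]]
    if (length(dim(first)) == 3L) {
        if (is.null(channel))
            stop("multi-channel stack (", dim(first)[3],
                 " samples/pixel): supply `channel` to select one")
        pages <- lapply(pages, function(p) p[, , channel])
        first <- pages[[1]]
    }
    ny <- nrow(first); nx <- ncol(first)
    arr <- array(0, c(length(pages), ny, nx))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    sp <- omeSpacing(attr(first, "description"))
    if (is.null(sp)) sp <- spacingOverride
    if (is.null(sp))
        stop("voxel spacing unknown: no OME PhysicalSize metadata in '",
             basename(path), "' and no spacingOverride given")
    VoxelGrid(arr, spacing = sp)
}

# parse (dz, dy, dx) um from an OME-XML ImageDescription, or NULL
omeSpacing <- function(desc) {
    if (is.null(desc) || !grepl("<OME", desc, fixed = TRUE)) return(NULL)
    doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
    if (is.null(doc)) return(NULL)
    xml2::xml_ns_strip(doc)
    px <- xml2::xml_find_first(doc, ".//Pixels")
    if (inherits(px, "xml_missing")) return(NULL)
    v <- vapply(c("PhysicalSizeZ", "PhysicalSizeY", "PhysicalSizeX"),
                function(a) as.numeric(xml2::xml_attr(px, a)), numeric(1))
    if (any(is.na(v))) return(NULL)
    unname(v)
}

#' Write a VoxelGrid as an OME-TIFF stack
#'
#' Writes an uncompressed, little-endian, 32-bit float grayscale OME-TIFF
#' with one page per z-plane and the voxel spacing recorded as
#' \code{PhysicalSizeX/Y/Z} in the OME-XML ImageDescription. Intensities
#' are stored in single precision; a written-then-read stack round-trips
#' bit-exactly thereafter.
#'
#' @param grid a [VoxelGrid-class].
#' @param path output path (conventionally \code{.ome.tif}).
#' @return \code{path}, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(grid, path) {
    stopifnot(is(grid, "VoxelGrid"))
    d <- dim(grid@intensities)
    nz <- d[1]; ny <- d[2]; nx <- d[3]
    desc <- omeDescription(nx, ny, nz, grid@spacing)
    descRaw <- c(charToRaw(enc2utf8(desc)), as.raw(0))
    descLen <- length(descRaw)  # ASCII count includes one NUL, not the pad
    if (length(descRaw) %% 2L == 1L) descRaw <- c(descRaw, as.raw(0))
    planeBytes <- ny * nx * 4L
    descOff <- 8L
    dataOff <- descOff + length(descRaw)
    ifdOff <- dataOff + nz * planeBytes
    con <- file(path, "wb")
    on.exit(close(con))
    wb <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
    # header
    writeBin(charToRaw("II"), con)
    wb(42L, 2L); wb(ifdOff, 4L)
    writeBin(descRaw, con)
    for (z in seq_len(nz))  # strip data, row-major (y rows of x)
        writeBin(as.numeric(t(grid@intensities[z, , ])), con, size = 4L,
                 endian = "little")
    # IFDs
    entry <- function(tag, type, count, value) {
        wb(tag, 2L); wb(type, 2L); wb(count, 4L)
        if (type == 3L && count == 1L) { wb(value, 2L); wb(0L, 2L) }
        else wb(value, 4L)
    }
    ifdSize <- function(n) 2L + n * 12L + 4L
    for (z in seq_len(nz)) {
        firstPage <- z == 1L
        n <- if (firstPage) 11L else 10L
        wb(n, 2L)
        entry(256L, 4L, 1L, nx)                      # ImageWidth
        entry(257L, 4L, 1L, ny)                      # ImageLength
        entry(258L, 3L, 1L, 32L)                     # BitsPerSample
        entry(259L, 3L, 1L, 1L)                      # Compression: none
        entry(262L, 3L, 1L, 1L)                      # Photometric: min-is-black
        if (firstPage)
            entry(270L, 2L, descLen, descOff)        # ImageDescription
        entry(273L, 4L, 1L, dataOff + (z - 1L) * planeBytes) # StripOffsets
        entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
        entry(278L, 4L, 1L, ny)                      # RowsPerStrip
        entry(279L, 4L, 1L, planeBytes)              # StripByteCounts
        entry(339L, 3L, 1L, 3L)                      # SampleFormat: IEEE float
        nxt <- if (z == nz) 0L else
            ifdOff + ifdSize(11L) + (z - 1L) * ifdSize(10L)
        wb(nxt, 4L)
    }
    invisible(path)
}

omeDescription <- function(nx, ny, nz, spacing) {
    paste0(
        '<?xml version="1.0" encoding="UTF-8"?>',
        '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
        '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYZCT"',
        ' Type="float" SizeX="', nx, '" SizeY="', ny, '" SizeZ="', nz,
        '" SizeC="1" SizeT="1"',
        sprintf(' PhysicalSizeX="%.10g" PhysicalSizeXUnit="µm"',
                spacing[3]),
        sprintf(' PhysicalSizeY="%.10g" PhysicalSizeYUnit="µm"',
                spacing[2]),
        sprintf(' PhysicalSizeZ="%.10g" PhysicalSizeZUnit="µm"',
                spacing[1]),
        '><TiffData/></Pixels></Image></OME>')
}

#' Read / write per-islet volume tables
#'
#' A volume table holds per-islet volumes from one or more imaging
#' modalities, with columns \code{sample_id}, \code{islet_id},
#' \code{volume_um3} (cubic micrometres, > 0) and \code{modality}. It is
#' the exchange format of the cross-modality concordance analysis: volumes
#' measured by a second technique (e.g. optical projection tomography) are
#' consumed as such a table, never re-derived from images.
#'
#' @param path CSV path.
#' @param table a data.frame with the four columns above.
#' @return \code{readVolumeTable} returns the validated data.frame;
#'   \code{writeVolumeTable} returns \code{path} invisibly.
#' @export
readVolumeTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    validateVolumeTable(df)
    df
}

#' @rdname readVolumeTable
#' @export
writeVolumeTable <- function(table, path) {
    validateVolumeTable(table)
    utils::write.csv(table, path, row.names = FALSE)
    invisible(path)
}

validateVolumeTable <- function(df) {
    need <- c("sample_id", "islet_id", "volume_um3", "modality")
    if (!all(need %in% names(df)))
        stop("volume table must have columns: ", paste(need, collapse = ", "))
    if (any(!is.finite(df$volume_um3)) || any(df$volume_um3 <= 0))
        stop("volumes must be positive and finite")
    key <- paste(df$sample_id, df$islet_id, df$modality, sep = "\r")
    if (anyDuplicated(key))
        stop("(sample_id, islet_id, modality) must be unique")
    invisible(df)
}

#' Write / read analysis record tables
#'
#' CSV persistence for the record data.frames produced by the pipeline
#' (morphometry, intensity, growth, concordance rows). Numeric fields are
#' serialized with 17 significant digits so a write-then-read round-trip
#' is lossless.
#'
#' @param records non-empty data.frame of records.
#' @param path CSV path.
#' @return \code{writeResults} returns \code{path} invisibly;
#'   \code{readResults} the data.frame.
#' @export
writeResults <- function(records, path) {
    if (!is.data.frame(records) || nrow(records) == 0L)
        stop("records must be a non-empty data.frame")
    out <- records
    for (j in seq_along(out))
        if (is.double(out[[j]]))
            out[[j]] <- sprintf("%.17g", out[[j]])
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
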