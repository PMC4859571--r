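
# Minimal NRRD support for dense volumes. Only the subset the package writes
# is read back: 3-D arrays, ascii encoding (so the artifacts stay text),
# axis-aligned spacings and an optional space origin. The first NRRD axis is
# the fastest-varying, which matches R's column-major array layout.

#' Write a 3-D array as an ASCII-encoded NRRD volume
#'
#' @param x 3-D numeric (or integer) array.
#' @param path Output file path.
#' @param voxel_size_um Voxel edge length (um), written as per-axis spacings.
#' @param origin_um Physical coordinate of the centre of voxel (1,1,1).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, voxel_size_um = 1, origin_um = c(0, 0, 0)) {
  if (length(dim(x)) != 3L) ls_abort("write_nrrd expects a 3-D array", "bad_volume")
  type <- if (is.integer(x)) "int" else "double"
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(x), collapse = " ")),
    "encoding: ascii",
    "space dimension: 3",
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            voxel_size_um, voxel_size_um, voxel_size_um),
    sprintf("space origin: (%g,%g,%g)", origin_um[1], origin_um[2], origin_um[3]),
    ""
  )
  vals <- if (type == "int") format(as.vector(x)) else
    format(as.vector(x), digits = 17, trim = TRUE, scientific = TRUE)
  body <- vapply(split(vals, ceiling(seq_along(vals) / 8)),
                 paste, character(1), collapse = " ")
  writeLines(c(header, unname(body)), path)
  invisible(path)
}

#' Read an ASCII-encoded NRRD volume
#'
#' @param path NRRD file written by [write_nrrd()] (or any 3-D ascii NRRD
#'   with uniform axis-aligned spacings).
#' @return List with `data` (3-D array), `voxel_size_um`, `origin_um`.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "NRRD")) {
    ls_abort(paste0("not a NRRD file: ", path), "bad_volume")
  }
  blank <- which(lines == "")[1]
  if (is.na(blank)) ls_abort("NRRD header not terminated by blank line", "bad_volume")
  header <- lines[2:(blank - 1)]
  header <- header[!startsWith(header, "#")]
  keys <- sub(":.*$", "", header)
  vals <- trimws(sub("^[^:]*:", "", header))
  field <- function(k) vals[match(k, keys)]

  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L) ls_abort("only 3-D NRRD volumes are supported", "bad_volume")
  enc <- field("encoding")
  if (!enc %in% c("ascii", "text", "txt")) {
    ls_abort(paste0("unsupported NRRD encoding: ", enc), "bad_volume")
  }
  nums <- function(s) as.numeric(regmatches(s, gregexpr("[-0-9.eE+]+", s))[[1]])
  spacing <- 1
  if (!is.na(field("space directions"))) {
    dirs <- nums(field("space directions"))
    spacing <- max(abs(dirs))
  } else if (!is.na(field("spacings"))) {
    spacing <- nums(field("spacings"))[1]
  }
  origin <- c(0, 0, 0)
  if (!is.na(field("space origin"))) origin <- nums(field("space origin"))

  data <- scan(text = lines[(blank + 1):length(lines)], quiet = TRUE)
  if (length(data) != prod(sizes)) {
    ls_abort(sprintf("NRRD payload has %d values, expected %d",
                     length(data), prod(sizes)), "bad_volume")
  }
  typ <- field("type")
  if (!is.na(typ) && typ %in% c("int", "short", "uchar", "long")) {
    data <- as.integer(data)
  }
  list(data = array(data, dim = sizes), voxel_size_um = spacing, origin_um = origin)
}
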