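#' Read a 4D multi-echo NIfTI image
#'
#' @param path NIfTI-1/2 file with echoes along the 4th dimension
#' @param protocol optional [t2_protocol()]; when given, the echo count is
#'   validated against it
#' @return list with `data` (4D numeric array), `voxel_mm` (length 3) and
#'   the underlying `image` object (affine preserved for round-trips)
#' @export
read_multiecho_nifti <- function(path, protocol = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4)
    stop(sprintf("expected a 4D multi-echo image%s, got %dD",
                 if (is.null(protocol)) ""
                 else sprintf(" with %d echoes", protocol$n_echoes),
                 length(d)))
  if (!is.null(protocol) && d[4] != protocol$n_echoes)
    stop(sprintf("echo dimension is %d, protocol expects %d", d[4],
                 protocol$n_echoes))
  list(data = array(as.numeric(img), d),
       voxel_mm = RNifti::pixdim(img)[1:3], image = img)
}

#' Write a scalar map as NIfTI
#'
#' @param map 3D numeric array
#' @param path output path
#' @param voxel_mm voxel size in mm
#' @return invisibly, `path`
#' @export
write_scalar_nifti <- function(map, path, voxel_mm = 1.6) {
  voxel_mm <- rep(voxel_mm, length.out = 3)
  nif <- RNifti::asNifti(map)
  RNifti::pixdim(nif) <- voxel_mm
  RNifti::writeNifti(nif, path)
  invisible(path)
}
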