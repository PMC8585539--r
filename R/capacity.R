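# Storage-capacity arithmetic for hermetic DNA capsules. All byte multiples
# are decimal SI (MB = 1e6, EB = 1e18, ZB = 1e21). Rounding happens only at
# report time; the internal chain carries unrounded values.

#' Physical and informational constants of a storage capsule
#'
#' Defaults describe a stainless-steel hermetic capsule: 200 uL useful
#' volume, DNA packed at 1.4 g/mL, capsule mass 1.3 g, an information
#' density of 17 EB per gram of DNA, and an average file size of 3 MB.
#'
#' @param useful_volume_ul Useful internal volume, microlitres.
#' @param dna_density_g_ml Density of packed DNA, g/mL.
#' @param capsule_mass_g Mass of one empty capsule, grams.
#' @param data_density_bytes_g Bytes storable per gram of DNA.
#' @param avg_file_size_bytes Average file size, bytes.
#' @return An object of class `capsule_spec`.
#' @export
capsule_spec <- function(useful_volume_ul = 200,
                         dna_density_g_ml = 1.4,
                         capsule_mass_g = 1.3,
                         data_density_bytes_g = 17e18,
                         avg_file_size_bytes = 3e6) {
  vals <- c(useful_volume_ul, dna_density_g_ml, capsule_mass_g,
            data_density_bytes_g, avg_file_size_bytes)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all capsule_spec fields must be strictly positive", call. = FALSE)
  structure(
    list(useful_volume_ul = useful_volume_ul,
         dna_density_g_ml = dna_density_g_ml,
         capsule_mass_g = capsule_mass_g,
         data_density_bytes_g = data_density_bytes_g,
         avg_file_size_bytes = avg_file_size_bytes),
    class = "capsule_spec"
  )
}

#' DNA mass one capsule can hold
#'
#' @param spec A [capsule_spec()].
#' @return Grams of DNA per capsule (volume in mL times density).
#' @examples
#' dna_mass_per_capsule(capsule_spec()) # 0.28 g
#' @export
dna_mass_per_capsule <- function(spec = capsule_spec()) {
  stopifnot(inherits(spec, "capsule_spec"))
  spec$useful_volume_ul / 1000 * spec$dna_density_g_ml
}

#' Data capacity of one capsule
#'
#' @param spec A [capsule_spec()].
#' @return A list with `bytes` (mass times data density) and `files`
#'   (bytes over average file size).
#' @examples
#' data_per_capsule(capsule_spec()) # 4.76e18 bytes, ~1.6e12 files
#' @export
data_per_capsule <- function(spec = capsule_spec()) {
  bytes <- dna_mass_per_capsule(spec) * spec$data_density_bytes_g
  list(bytes = bytes, files = bytes / spec$avg_file_size_bytes)
}

#' Plan capsule storage for a data volume
#'
#' Converts a total byte count into DNA mass, capsule count and shipment
#' mass. The capsule count is rounded to the nearest integer by default
#' (`rounding = "ceiling"` guarantees the plan physically holds the data);
#' all other quantities are carried unrounded.
#'
#' @param total_bytes Total data volume in bytes (> 0), decimal SI.
#' @param spec A [capsule_spec()].
#' @param rounding `"nearest"` (default) or `"ceiling"` for the capsule
#'   count.
#' @return An object of class `storage_plan` with fields `total_bytes`,
#'   `dna_mass_g`, `n_capsules`, `total_mass_kg`.
#' @examples
#' plan_storage(64e21) # 64 ZB: ~3765 g of DNA, 13,445 capsules, ~21 kg
#' @export
plan_storage <- function(total_bytes, spec = capsule_spec(),
                         rounding = c("nearest", "ceiling")) {
  stopifnot(inherits(spec, "capsule_spec"))
  rounding <- match.arg(rounding)
  if (length(total_bytes) != 1L || !is.finite(total_bytes) || total_bytes <= 0)
    stop("total_bytes must be a single positive number", call. = FALSE)
  dna_mass_g <- total_bytes / spec$data_density_bytes_g
  n_raw <- dna_mass_g / dna_mass_per_capsule(spec)
  n_capsules <- if (rounding == "nearest") round(n_raw) else ceiling(n_raw)
  structure(
    list(total_bytes = total_bytes,
         dna_mass_g = dna_mass_g,
         n_capsules = n_capsules,
         total_mass_kg = (n_capsules * spec$capsule_mass_g + dna_mass_g) / 1000,
         rounding = rounding),
    class = "storage_plan"
  )
}

#' @export
print.storage_plan <- function(x, ...) {
  cat(sprintf("Storage plan for %.3g bytes:\n", x$total_bytes))
  cat(sprintf("  DNA mass:   %.0f g\n", x$dna_mass_g))
  cat(sprintf("  capsules:   %s (%s rounding)\n",
              format(x$n_capsules, big.mark = ","), x$rounding))
  cat(sprintf("  total mass: %.0f kg\n", x$total_mass_kg))
  invisible(x)
}
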