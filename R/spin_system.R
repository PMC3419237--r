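#' Construct an S = 1/2 spin system
#'
#' Bundles the principal values of the g-tensor, an optional set of
#' hyperfine-coupled nuclei and per-axis Gaussian linewidths into the
#' parameter object consumed by [powder_spectrum()] and [fit_spin_system()].
#' Hyperfine tensors are assumed collinear with the g-tensor principal frame.
#'
#' @param name label for the species.
#' @param g numeric length-3 vector of principal g-values, ordered
#'   `g1 >= g2 >= g3`.
#' @param hyperfine list of couplings, each a list with elements `label`
#'   (text), `I` (nuclear spin, half-integer, default 1/2) and `A` (length-3
#'   principal values in Gauss; signs are kept but only magnitudes enter the
#'   first-order splitting). At most 8 nuclei (the transition count grows as
#'   `prod(2I+1)`).
#' @param linewidth numeric length-3 peak-to-peak Gaussian linewidths along
#'   the three principal axes, in Gauss; all positive.
#'
#' @return An object of class `spin_system`.
#' @seealso [preset_spin_system()] for literature parameter sets.
#' @export
#' @examples
#' sys <- spin_system("iso", g = c(2.005, 2.005, 2.005), linewidth = c(5, 5, 5))
#' sys
spin_system <- function(name, g, hyperfine = list(), linewidth) {
  if (!is.numeric(g) || length(g) != 3L || any(!is.finite(g)))
    stop("'g' must be three finite principal values")
  if (any(g <= 1.0) || any(g >= 3.0))
    stop("principal g-values outside (1, 3); not an S = 1/2 system in scope")
  if (is.unsorted(rev(g)))
    stop("principal g-values must be ordered g1 >= g2 >= g3")
  if (!is.numeric(linewidth) || length(linewidth) != 3L ||
      any(!is.finite(linewidth)) || any(linewidth <= 0))
    stop("'linewidth' must be three positive peak-to-peak widths in Gauss")
  if (!is.list(hyperfine))
    stop("'hyperfine' must be a list of couplings")
  if (length(hyperfine) > 8L)
    stop("at most 8 hyperfine nuclei supported (2^n transition bound)")
  hyperfine <- lapply(seq_along(hyperfine), function(i) {
    h <- hyperfine[[i]]
    if (is.null(h$A) || length(h$A) != 3L || any(!is.finite(h$A)))
      stop("hyperfine entry ", i, ": 'A' must be three finite values (Gauss)")
    I <- if (is.null(h$I)) 0.5 else h$I
    if (!is.numeric(I) || I <= 0 || abs(2 * I - round(2 * I)) > 1e-9)
      stop("hyperfine entry ", i, ": nuclear spin must be a positive half-integer")
    list(label = if (is.null(h$label)) paste0("H", i) else as.character(h$label),
         I = I, A = as.numeric(h$A))
  })
  structure(list(name = as.character(name), g = as.numeric(g),
                 hyperfine = hyperfine,
                 linewidth = as.numeric(linewidth)),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("S = 1/2 spin system:", x$name, "\n")
  cat(sprintf("  g = %.4f, %.4f, %.4f\n", x$g[1], x$g[2], x$g[3]))
  if (length(x$hyperfine)) {
    cat("  hyperfine couplings (G):\n")
    for (h in x$hyperfine)
      cat(sprintf("    %-8s I = %g  A = %.1f, %.1f, %.1f\n",
                  h$label, h$I, h$A[1], h$A[2], h$A[3]))
  } else cat("  no resolved hyperfine structure\n")
  cat(sprintf("  peak-to-peak linewidths (G): %.4g, %.4g, %.4g\n",
              x$linewidth[1], x$linewidth[2], x$linewidth[3]))
  invisible(x)
}

## Tyrosyl radicals in class Ia RNR share, to first order, the mouse R2
## beta-methylene and 3,5-ring proton hyperfine set; only g1 varies
## appreciably with the hydrogen-bonding environment of the phenoxyl oxygen.
.TYROSYL_HYPERFINE <- list(
  list(label = "beta1",  I = 0.5, A = c(21.4, 19.0, 21.5)),
  list(label = "beta2",  I = 0.5, A = c(9.5, 2.5, 5.7)),
  list(label = "ring35_1", I = 0.5, A = c(-9.1, -4.4, -6.6)),
  list(label = "ring35_2", I = 0.5, A = c(-7.3, -4.8, -5.8))
)
.TYROSYL_LINEWIDTH <- c(4.5, 3.5, 4.4)

## Mixed-valent Fe(II)Fe(III) centres: only g-values are characterised;
## the broad envelopes are represented by a default 100 G (10 mT)
## peak-to-peak width per axis, overridable after construction.
.MV_LINEWIDTH <- c(100, 100, 100)

.PRESETS <- list(
  carp_R2i       = list(g = c(2.0073, 2.0042, 2.0022), kind = "tyrosyl"),
  carp_R2ii      = list(g = c(2.0073, 2.0041, 2.0022), kind = "tyrosyl"),
  carp_p53R2i    = list(g = c(2.0074, 2.0042, 2.0022), kind = "tyrosyl"),
  carp_p53R2ii   = list(g = c(2.0074, 2.0042, 2.0022), kind = "tyrosyl"),
  mouse_R2       = list(g = c(2.0076, 2.0043, 2.0022), kind = "tyrosyl"),
  human_p53R2    = list(g = c(2.0074, 2.0042, 2.0021), kind = "tyrosyl"),
  mouse_p53R2    = list(g = c(2.0078, 2.0043, 2.0022), kind = "tyrosyl"),
  mv_carp_R2ii   = list(g = c(1.92, 1.73, 1.61), kind = "mixed_valent"),
  mv_carp_p53R2ii = list(g = c(1.91, 1.72, 1.61), kind = "mixed_valent"),
  mv_mouse_R2    = list(g = c(1.92, 1.73, 1.60), kind = "mixed_valent"),
  mv_mouse_p53R2 = list(g = c(1.91, 1.72, 1.59), kind = "mixed_valent"),
  mv_human_p53R2 = list(g = c(1.90, 1.72, 1.60), kind = "mixed_valent"),
  ## Cu(II)-EDTA spin standard: broad axial-like envelope; modelled as a
  ## featureless S = 1/2 line since only its double integral is used.
  cu_edta_standard = list(g = c(2.31, 2.07, 2.07), kind = "standard",
                          linewidth = c(400, 400, 400))
)

#' Literature spin systems for RNR small subunits
#'
#' Returns a ready-made [spin_system()] for the tyrosyl radicals of crucian
#' carp, mouse and human RNR R2/p53R2 subunits, their mixed-valent
#' Fe(II)Fe(III) di-iron centres (prefix `mv_`), or the Cu(II)-EDTA
#' concentration standard. Tyrosyl presets carry the shared mouse-R2 proton
#' hyperfine set and 4.5/3.5/4.4 G linewidths; mixed-valent presets carry no
#' hyperfine structure and a default 100 G per-axis width.
#'
#' @param name one of `"carp_R2i"`, `"carp_R2ii"`, `"carp_p53R2i"`,
#'   `"carp_p53R2ii"`, `"mouse_R2"`, `"human_p53R2"`, `"mouse_p53R2"`,
#'   `"mv_carp_R2ii"`, `"mv_carp_p53R2ii"`, `"mv_mouse_R2"`,
#'   `"mv_mouse_p53R2"`, `"mv_human_p53R2"`, `"cu_edta_standard"`.
#' @return A `spin_system`.
#' @export
#' @examples
#' preset_spin_system("mouse_R2")$g
#' preset_spin_system("mv_carp_R2ii")
preset_spin_system <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.PRESETS))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available: ", paste(names(.PRESETS), collapse = ", "))
  p <- .PRESETS[[name]]
  if (p$kind == "tyrosyl") {
    spin_system(name, p$g, .TYROSYL_HYPERFINE, .TYROSYL_LINEWIDTH)
  } else if (p$kind == "mixed_valent") {
    spin_system(name, p$g, list(), .MV_LINEWIDTH)
  } else {
    spin_system(name, p$g, list(), p$linewidth)
  }
}

#' Read or write a spin system as JSON
#'
#' The on-disk format uses keys `name`, `g` (three principal values),
#' `hyperfine` (array of objects with `label`, `I`, `A_G`) and
#' `linewidth_G`, with couplings and widths in Gauss.
#'
#' @param path file path.
#' @return `read_spin_system()` returns a `spin_system`;
#'   `write_spin_system()` invisibly returns `path`.
#' @export
read_spin_system <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$g) || is.null(x$linewidth_G))
    stop("spin-system JSON needs keys 'g' and 'linewidth_G': ", path)
  hf <- list()
  if (!is.null(x$hyperfine) && length(x$hyperfine)) {
    hfin <- x$hyperfine
    if (is.data.frame(hfin)) {
      hf <- lapply(seq_len(nrow(hfin)), function(i)
        list(label = hfin$label[i],
             I = if ("I" %in% names(hfin)) hfin$I[i] else 0.5,
             A = as.numeric(hfin$A_G[[i]])))
    } else {
      hf <- lapply(hfin, function(h)
        list(label = h$label, I = if (is.null(h$I)) 0.5 else h$I,
             A = as.numeric(h$A_G)))
    }
  }
  spin_system(if (is.null(x$name)) "unnamed" else x$name,
              as.numeric(x$g), hf, as.numeric(x$linewidth_G))
}

#' @param system a `spin_system`.
#' @rdname read_spin_system
#' @export
write_spin_system <- function(system, path) {
  stopifnot(inherits(system, "spin_system"))
  out <- list(name = system$name, g = system$g,
              hyperfine = lapply(system$hyperfine, function(h)
                list(label = h$label, I = h$I, A_G = h$A)),
              linewidth_G = system$linewidth)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
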