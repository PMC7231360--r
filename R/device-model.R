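#' IDE cell constant
#'
#' Theoretical cell constant of a simple interdigitated electrode array,
#' K = 2 S / (3 W L (N - 1)), where S is the spacing between fingers, W the
#' finger width, L the finger length and N the number of fingers.  The cell
#' constant is the reciprocal-length geometry factor relating measured
#' resistance to medium resistivity; lower K means higher sensitivity to
#' cell-layer changes.
#'
#' @param geom an \linkS4class{IDEGeometry}
#' @return cell constant K in cm^-1 (lengths are SI meters internally;
#'   the conventional cm^-1 is used only at this boundary)
#' @examples
#' cellConstant(IDEGeometry(100e-6, 100e-6, 2e-3, 30))  # 0.1149 cm^-1
#' @export
cellConstant <- function(geom) {
    validObject(geom)
    kPerM <- 2 * geom@fingerSpacing /
        (3 * geom@fingerWidth * geom@fingerLength * (geom@nFingers - 1))
    kPerM / 100
}

#' Cantilever spring constant
#'
#' Stiffness of an end-loaded rectangular cantilever,
#' k = E w t^3 / (4 L^3).  When the \linkS4class{CantileverSpec} was built
#' with an explicit `springConstant` override, that value is returned.
#'
#' @param spec a \linkS4class{CantileverSpec}
#' @return spring constant k (N/m)
#' @examples
#' # 6 mm x 2 mm x 15 um SU-8 beam (E = 2 GPa): k = 0.015625 N/m,
#' # i.e. 0.015 N/m to two significant figures.
#' springConstant(CantileverSpec(6e-3, 2e-3, 15e-6))
#' @export
springConstant <- function(spec) {
    validObject(spec)
    spec@springConstant
}

#' Displacement to force
#'
#' Hookean conversion of cantilever tip displacement to contraction force,
#' F = k * delta.  The force-displacement relation of the device is linear
#' over the working range, so a 500 nm deflection of a 0.015 N/m beam reads
#' 7.5 nN and 50 um reads 750 nN.  Negative displacements (opposite
#' deflection direction) are allowed.
#'
#' @param k spring constant (N/m), > 0
#' @param delta tip displacement (m), vectorized
#' @return force (N)
#' @export
forceFromDisplacement <- function(k, delta) {
    if (length(k) != 1L || !is.finite(k) || k <= 0)
        .stopf("spring constant k must be a single positive number")
    if (any(is.na(delta)) || any(!is.finite(delta)))
        .stopf("displacement must be finite (no NaN/NA)")
    k * delta
}

#' Force to displacement
#'
#' Exact inverse of [forceFromDisplacement()]: delta = F / k.
#'
#' @param k spring constant (N/m), > 0
#' @param force tip force (N), vectorized
#' @return displacement (m)
#' @export
displacementFromForce <- function(k, force) {
    if (length(k) != 1L || !is.finite(k) || k <= 0)
        .stopf("spring constant k must be a single positive number")
    if (any(is.na(force)) || any(!is.finite(force)))
        .stopf("force must be finite (no NaN/NA)")
    force / k
}
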