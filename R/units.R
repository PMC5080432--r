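#' Unit conversions between SI and conventional AUC units
#'
#' All internal computation in aucbind is in SI (seconds, metres, kg/m^3,
#' mol/L for concentrations). Data tables and plots use the conventional
#' units of the sedimentation literature: Svedberg (1 S = 1e-13 s), g/cm^3,
#' nm and micromolar. These helpers convert explicitly between the two.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' seconds_to_sv(5.55e-12) # ~ 55.5 S
#' g_cm3_to_kg_m3(5.5)     # 5500 kg/m^3
#' @name units
NULL

#' @rdname units
#' @export
sv_to_seconds <- function(x) x / 1e13

#' @rdname units
#' @export
seconds_to_sv <- function(x) x * 1e13

#' @rdname units
#' @export
g_cm3_to_kg_m3 <- function(x) x * 1000

#' @rdname units
#' @export
kg_m3_to_g_cm3 <- function(x) x / 1000

#' @rdname units
#' @export
nm_to_m <- function(x) x / 1e9

#' @rdname units
#' @export
m_to_nm <- function(x) x * 1e9

#' @rdname units
#' @export
nm3_to_m3 <- function(x) x / 1e27

#' @rdname units
#' @export
m3_to_nm3 <- function(x) x * 1e27

#' @rdname units
#' @export
molar_to_um <- function(x) x * 1e6

#' @rdname units
#' @export
um_to_molar <- function(x) x / 1e6
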