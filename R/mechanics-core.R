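#' Construct an elastic layer
#'
#' An elastic layer is the basic mechanical building block of the trilayer
#' biofilm model: a neo-Hookean solid characterised by its shear modulus,
#' thickness and Poisson ratio. All quantities are strict SI (Pa, m);
#' dimensionless ratios are the canonical computational representation and
#' absolute values are views onto them.
#'
#' @param G Shear modulus in Pa. Must be positive.
#' @param h Thickness in m. Must be non-negative (a zero-thickness residual
#'   layer recovers the bilayer model).
#' @param nu Poisson ratio. The linear-stability theory admits the
#'   incompressible value 0.5; finite-element use requires `nu < 0.5`.
#' @return An object of class `elastic_layer`: a named list with fields
#'   `G`, `h`, `nu`.
#' @examples
#' film <- elastic_layer(G = 1500, h = 100e-6, nu = 0.5)
#' @export
elastic_layer <- function(G, h, nu = 0.5) {
  stopifnot(is.numeric(G), is.numeric(h), is.numeric(nu))
  if (G <= 0) abort("`G` must be positive.", class = "biofilmorph_domain_error")
  if (h < 0) abort("`h` must be non-negative.", class = "biofilmorph_domain_error")
  if (nu <= 0 && nu != 0 || nu > 0.5)
    abort("`nu` must lie in (0, 0.5], or be exactly 0 for test use.",
          class = "biofilmorph_domain_error")
  structure(list(G = as.numeric(G), h = as.numeric(h), nu = as.numeric(nu)),
            class = "elastic_layer")
}

#' Construct a trilayer stack
#'
#' Bundles the three elastic components of the biofilm system: the biofilm
#' film on top, the thin soft residual layer left on the agar beneath it, and
#' the thick agar substrate.
#'
#' @param film,residual,substrate [elastic_layer()] objects.
#' @param check_fem If `TRUE`, additionally enforce the thick-substrate
#'   assumption (`substrate$h >= 5 * film$h`) and compressible Poisson ratios
#'   required by the finite-element model.
#' @return An object of class `layer_stack`.
#' @examples
#' stk <- layer_stack(
#'   film      = elastic_layer(G = 1000, h = 1),
#'   residual  = elastic_layer(G = 100, h = 0.3),
#'   substrate = elastic_layer(G = 100, h = 10)
#' )
#' @export
layer_stack <- function(film, residual, substrate, check_fem = FALSE) {
  for (ly in list(film, residual, substrate))
    if (!inherits(ly, "elastic_layer"))
      abort("All layers must be `elastic_layer` objects.")
  if (check_fem) {
    if (substrate$h < 5 * film$h)
      abort("FEM use requires a thick substrate: substrate$h >= 5 * film$h.",
            class = "biofilmorph_domain_error")
    for (ly in list(film, residual, substrate))
      if (ly$nu >= 0.5)
        abort("FEM use requires nu < 0.5 in every layer.",
              class = "biofilmorph_domain_error")
  }
  structure(list(film = film, residual = residual, substrate = substrate),
            class = "layer_stack")
}

#' Build a trilayer stack from dimensionless ratios
#'
#' Results in this field are reported as ratios (`G_f/G_s`, `lambda/h_f`), so
#' the natural parameterisation fixes the film at unit modulus and thickness
#' and expresses the other layers relative to it.
#'
#' @param gf_over_gs Film-to-substrate stiffness contrast `G_f/G_s`.
#' @param gr_over_gf Residual-to-film stiffness ratio `G_r/G_f` (default 0.1,
#'   the value that best fits measured biofilm wavelengths).
#' @param hr_over_hf Residual-to-film thickness ratio (default 0.3, the
#'   measured average).
#' @param hs_over_hf Substrate-to-film thickness ratio (default 10).
#' @param nu Poisson ratio applied to all three layers.
#' @param G_f,h_f Absolute film modulus (Pa) and thickness (m); defaults give
#'   the dimensionless stack.
#' @return A `layer_stack`.
#' @export
stack_from_ratios <- function(gf_over_gs, gr_over_gf = 0.1, hr_over_hf = 0.3,
                              hs_over_hf = 10, nu = 0.5, G_f = 1, h_f = 1) {
  if (gf_over_gs <= 0) abort("`gf_over_gs` must be positive.",
                             class = "biofilmorph_domain_error")
  layer_stack(
    film      = elastic_layer(G = G_f, h = h_f, nu = nu),
    residual  = elastic_layer(G = gr_over_gf * G_f, h = hr_over_hf * h_f, nu = nu),
    substrate = elastic_layer(G = G_f / gf_over_gs, h = hs_over_hf * h_f, nu = nu)
  )
}

#' Growth-induced mismatch strain
#'
#' A film that has grown by a linear factor `1 + g` while attached to a
#' non-growing substrate carries a compressive mismatch strain
#' `epsilon = g / (1 + g)`.
#'
#' @param g Growth parameter, `g >= 0`. Vectorised.
#' @return The mismatch strain, in `[0, 1)`.
#' @examples
#' growth_strain(c(0, 1, 0.002))
#' @export
growth_strain <- function(g) {
  if (any(g < 0)) abort("`g` must be non-negative.",
                        class = "biofilmorph_domain_error")
  g / (1 + g)
}

#' Growth state at a given growth parameter
#'
#' @param g Growth parameter.
#' @return A one-row tibble with `g`, the mismatch strain `epsilon`, and the
#'   growth volume factor `J_g = 1 + g` (area factor of the plane-strain
#'   uniaxial growth tensor `diag(1 + g, 1)`).
#' @export
growth_state <- function(g) {
  tibble(g = g, epsilon = growth_strain(g), J_g = 1 + g)
}

#' Lame parameters of a compressible neo-Hookean layer
#'
#' @param G Shear modulus (Pa).
#' @param nu Poisson ratio in `[0, 0.5)`; the incompressible limit is not
#'   representable (`lambda_e` diverges).
#' @return A named list with `mu_e = G` and `lambda_e = 2 G nu / (1 - 2 nu)`.
#' @examples
#' lame_parameters(1, 0.45) # mu_e = 1, lambda_e = 9
#' @export
lame_parameters <- function(G, nu) {
  if (any(G <= 0)) abort("`G` must be positive.", class = "biofilmorph_domain_error")
  if (any(nu < 0) || any(nu >= 0.5))
    abort("`nu` must lie in [0, 0.5): the incompressible limit is not representable.",
          class = "biofilmorph_domain_error")
  list(mu_e = G, lambda_e = 2 * G * nu / (1 - 2 * nu))
}

#' Poisson ratio from bulk and shear moduli
#'
#' Rheometry on biofilm material yields a bulk modulus `K` (from uniaxial
#' piston compression) and a plateau storage shear modulus `G`; the Poisson
#' ratio follows from linear elasticity as `(3K - 2G) / (2 (3K + G))`.
#'
#' @param K Bulk modulus (Pa), positive.
#' @param G Shear modulus (Pa), non-negative (zero gives the incompressible
#'   limit 0.5 exactly).
#' @return The Poisson ratio, at most 0.5.
#' @examples
#' poisson_from_moduli(130e3, 1.3e3) # ~0.495
#' @export
poisson_from_moduli <- function(K, G) {
  if (any(K <= 0) || any(G < 0))
    abort("`K` must be positive and `G` non-negative.",
          class = "biofilmorph_domain_error")
  (3 * K - 2 * G) / (2 * (3 * K + G))
}

#' Interfacial energy set
#'
#' The three interfacial energies that govern blister dynamics: the
#' film-substrate adhesion energy `Gamma` (the cost of delaminating), the
#' film-liquid energy `gamma_fl` of the blister underside, and the film-air
#' energy `gamma_fa` of its top. Zero values are allowed (matrix mutants have
#' adhesion below the detection limit).
#'
#' @param Gamma,gamma_fl,gamma_fa Energies per unit area (J/m^2), `>= 0`.
#' @return An object of class `interfacial_energy_set`.
#' @export
interfacial_energies <- function(Gamma, gamma_fl, gamma_fa) {
  vals <- c(Gamma, gamma_fl, gamma_fa)
  if (any(vals < 0)) abort("Interfacial energies must be non-negative.",
                           class = "biofilmorph_domain_error")
  structure(list(Gamma = Gamma, gamma_fl = gamma_fl, gamma_fa = gamma_fa),
            class = "interfacial_energy_set")
}

#' @export
print.elastic_layer <- function(x, ...) {
  cat(sprintf("<elastic_layer> G = %g Pa, h = %g m, nu = %g\n", x$G, x$h, x$nu))
  invisible(x)
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("<layer_stack>\n")
  for (nm in c("film", "residual", "substrate"))
    cat(sprintf("  %-9s G = %-10g h = %-10g nu = %g\n",
                nm, x[[nm]]$G, x[[nm]]$h, x[[nm]]$nu))
  invisible(x)
}

#' Tabulate a layer stack
#'
#' @param stack A `layer_stack`.
#' @return A tibble with columns `layer`, `G_Pa`, `h_m`, `nu`.
#' @export
stack_table <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  tibble(
    layer = c("film", "residual", "substrate"),
    G_Pa = vapply(stack[c("film", "residual", "substrate")], `[[`, 0, "G"),
    h_m  = vapply(stack[c("film", "residual", "substrate")], `[[`, 0, "h"),
    nu   = vapply(stack[c("film", "residual", "substrate")], `[[`, 0, "nu")
  )
}

#' Read / write layer parameter tables
#'
#' Layer tables use the header `layer,G_Pa,h_m,nu` (CSV) or the equivalent
#' JSON array of records; rows must be film, residual, substrate.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return `read_stack()` returns a `layer_stack`; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv  = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    abort("Unsupported extension (use .csv or .json).")
  )
  need <- c("layer", "G_Pa", "h_m", "nu")
  if (!all(need %in% names(df)))
    abort(sprintf("Layer table must have columns %s.", paste(need, collapse = ", ")))
  row_of <- function(nm) df[df$layer == nm, , drop = FALSE]
  mk <- function(nm) {
    r <- row_of(nm)
    if (nrow(r) != 1) abort(sprintf("Layer table needs exactly one '%s' row.", nm))
    elastic_layer(G = r$G_Pa, h = r$h_m, nu = r$nu)
  }
  layer_stack(mk("film"), mk("residual"), mk("substrate"))
}

#' @rdname read_stack
#' @param stack A `layer_stack` to serialise.
#' @export
write_stack <- function(stack, path) {
  df <- stack_table(stack)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv  = utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    json = jsonlite::write_json(df, path, digits = NA),
    abort("Unsupported extension (use .csv or .json).")
  )
  invisible(path)
}
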