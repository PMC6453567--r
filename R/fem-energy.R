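#' Neo-Hookean strain energy density
#'
#' Compressible plane-strain neo-Hookean energy of an elastic deformation
#' gradient:
#' \deqn{\Psi(F_e) = \frac{\mu_e}{2}(I_C - 2 - 2\ln J) + \frac{\lambda_e}{2}(\ln J)^2,}
#' with `I_C = tr(F_e^T F_e)` and `J = det F_e`. The energy vanishes at the
#' identity and is non-negative in its neighbourhood.
#'
#' @param F_e A 2x2 elastic deformation gradient with positive determinant.
#' @param mu_e,lambda_e Lame parameters (Pa), see [lame_parameters()].
#' @return The energy density (same units as the moduli).
#' @examples
#' neo_hookean_energy_density(diag(2), 1, 9) # 0
#' @export
neo_hookean_energy_density <- function(F_e, mu_e, lambda_e) {
  stopifnot(is.matrix(F_e), all(dim(F_e) == c(2, 2)))
  J <- F_e[1, 1] * F_e[2, 2] - F_e[1, 2] * F_e[2, 1]
  if (J <= 0) abort("det(F_e) must be positive (inverted element).",
                    class = "biofilmorph_inverted_element")
  IC <- sum(F_e^2)
  mu_e / 2 * (IC - 2 - 2 * log(J)) + lambda_e / 2 * log(J)^2
}

# flatten an n x 2 displacement matrix (or pass through a 2n vector)
as_u_vector <- function(u, mesh) {
  n <- nrow(mesh$nodes)
  if (is.matrix(u)) {
    stopifnot(nrow(u) == n, ncol(u) == 2)
    c(u[, 1], u[, 2])
  } else {
    stopifnot(length(u) == 2 * n)
    as.numeric(u)
  }
}

#' Total elastic energy of the grown trilayer
#'
#' Assembles \eqn{\Pi = \sum_e A_e \Psi(F_{e}) J_g} over all elements, with
#' the multiplicative growth split `F = F_e F_g`, `F_g = diag(1+g, 1)` in the
#' film and residual layers and the identity in the substrate. `F` is
#' constant per linear triangle, so the one-point rule is exact.
#'
#' @param u Displacements: an `n x 2` matrix (columns `u1`, `u2`) or a `2n`
#'   vector.
#' @param mesh A [build_mesh()] result.
#' @param config The [fem_config()] used to build the mesh.
#' @param g Growth parameter, `>= 0`.
#' @return The total energy (units `G_f h_f^2` per unit out-of-plane depth).
#' @export
total_energy <- function(u, mesh, config, g) {
  stopifnot(inherits(mesh, "fem_mesh"), g >= 0)
  uv <- as_u_vector(u, mesh)
  out <- .nh_energy_grad(uv, mesh$tri - 1L, mesh$bx, mesh$by, mesh$area,
                         mesh$mu, mesh$lam, mesh$grows, g, FALSE)
  if (isTRUE(out$inverted))
    abort("Inverted element encountered while evaluating the energy.",
          class = "biofilmorph_inverted_element")
  out$energy
}

# energy and gradient on the full dof vector (internal)
energy_grad_full <- function(uv, mesh, g) {
  .nh_energy_grad(uv, mesh$tri - 1L, mesh$bx, mesh$by, mesh$area,
                  mesh$mu, mesh$lam, mesh$grows, g, TRUE)
}

#' Per-element strain fields
#'
#' Post-processes a displacement field into per-element deformation and
#' strain measures: the Green-Lagrange strain `e = (F_e^T F_e - I)/2` of the
#' elastic part, its 2D deviator `e' = e - (tr e / 2) I`, and the von Mises
#' equivalent strain `eps_vM = sqrt(2 e'_ij e'_ij / 3)`.
#'
#' @inheritParams total_energy
#' @return A tibble with one row per element: centroid coordinates `x`, `y`,
#'   `label`, deformation invariants `J`, `I_C`, strain components `e11`,
#'   `e12`, `e22`, and `evm`.
#' @export
strain_fields <- function(u, mesh, config, g) {
  stopifnot(inherits(mesh, "fem_mesh"))
  uv <- as_u_vector(u, mesh)
  S <- .nh_strains(uv, mesh$tri - 1L, mesh$bx, mesh$by, mesh$grows, g)
  if (any(S[, 5] <= 0))
    abort(sprintf("Inverted element (first index %d).", which(S[, 5] <= 0)[1]),
          class = "biofilmorph_inverted_element")
  cx <- rowMeans(matrix(mesh$nodes[mesh$tri, 1], ncol = 3))
  cy <- rowMeans(matrix(mesh$nodes[mesh$tri, 2], ncol = 3))
  tibble(x = cx, y = cy, label = mesh$label,
         J = S[, 5], I_C = S[, 6],
         e11 = S[, 7], e12 = S[, 8], e22 = S[, 9], evm = S[, 10])
}
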