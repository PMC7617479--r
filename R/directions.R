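## 48 unit gradient directions, optimized once by minimizing the antipodal
## (line) Coulomb energy sum 1/(1 - (gi.gj)^2) over the sphere from a
## deterministic Fibonacci-lattice start (see optimize_directions). Signs are
## normalized to z >= 0; only g g^T matters for PGSE. Worst-case powder-average
## quadrature error of this set is ~0.4% at b = 5000 s/mm^2 (D_par = 2).
.DIRECTIONS48 <- matrix(c(
  0.038095905890525, -0.047961034252414, 0.998122457991913,
  -0.136347512405528, 0.286422716362243, 0.948351930146451,
  0.405058278223086, -0.118137363288964, 0.906626358892173,
  -0.372207057490198, -0.016748130447054, 0.927998602628806,
  0.099624207082135, 0.595700261482748, 0.797004526858312,
  0.513161528106335, -0.456730030109813, 0.726679382993257,
  -0.519888916199879, -0.361198231900389, 0.774113268252487,
  0.756347711570711, 0.374937354891577, 0.536059809264466,
  -0.091944789993781, -0.646238020195742, 0.757576779505871,
  -0.570883902591797, 0.596597088352889, 0.564059823006758,
  0.733215939404874, -0.121478526826801, 0.669057063128862,
  -0.685940534417946, -0.628316514887754, 0.367020354151822,
  -0.113249294933335, 0.830806198706703, 0.544918028135995,
  0.558625010415214, -0.722240168557803, 0.407807842813499,
  -0.804158450457504, 0.306573848458712, 0.509255988672692,
  0.888899520864254, 0.414436005269230, 0.195193338369376,
  -0.430407205498139, -0.866701192241937, 0.252148132695220,
  -0.230854046141632, 0.970876059666378, 0.064078749572112,
  0.809864516098439, -0.573979216472035, 0.121108730580374,
  -0.907545352091828, -0.382219031129062, 0.173982890363626,
  0.419491558177970, 0.898249316311348, 0.131053417977612,
  0.248317514474954, -0.918394455824450, 0.308042262548329,
  -0.940914147449798, 0.301448798662387, 0.154302264772178,
  0.997003337394154, 0.075841118180824, 0.015246967501816,
  0.625483576476292, 0.686519633863683, 0.370757451547640,
  -0.106651372968641, -0.987400575671940, 0.116899905075347,
  -0.745586281984264, 0.621201152078401, 0.241267952230190,
  0.949309989735454, -0.229447891530040, 0.214858577815483,
  0.715941500819377, 0.698158807540190, 0.001430684646598,
  0.073362745056274, 0.961698783235524, 0.264108610160896,
  0.555091663878124, -0.830882147115479, 0.038834292806567,
  -0.932886010765676, -0.018664193052511, 0.359687835234112,
  0.908937610096073, 0.071941263374329, 0.410678555048769,
  -0.097634801617412, -0.876740930506573, 0.470948814933850,
  -0.420211736163908, 0.840068589019399, 0.343084337347350,
  0.775159351492758, -0.421137981339765, 0.470925451070968,
  -0.784769468610988, -0.318776112259428, 0.531524854911595,
  0.290118387606532, 0.805384925826400, 0.516900805207528,
  0.255041750597247, -0.727449033999931, 0.637002047394558,
  -0.517726456925937, 0.300138083305467, 0.801171920843858,
  0.582197571967207, 0.183247219861957, 0.792127794997974,
  -0.420167183890916, -0.673531441066359, 0.608124111901717,
  -0.266665637549292, 0.587416685441322, 0.764088395027408,
  0.183161300775914, -0.415122551721026, 0.891137029278157,
  -0.704980146285871, -0.006706423917554, 0.709195330794690,
  0.455541493551530, 0.535805477938140, 0.710910991238933,
  -0.190775842027695, -0.336699615970418, 0.922083481418031,
  0.243194682586029, 0.265723824793252, 0.932870406486949),
  ncol = 3, byrow = TRUE)

## deterministic Fibonacci lattice on the sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

#' Near-uniform gradient direction sets
#'
#' Returns `n` unit vectors spread over the sphere for powder-average
#' acquisitions. For the default n = 48 a precomputed electrostatically
#' optimized antipodal set is returned (the set used by the phantom
#' simulator); other sizes are generated by [optimize_directions()].
#'
#' @param n number of directions
#' @return n x 3 matrix of unit row vectors
#' @export
dmri_directions <- function(n = 48) {
  if (n == 48) return(.DIRECTIONS48)
  optimize_directions(n)
}

#' Electrostatic-repulsion direction optimisation
#'
#' Minimises the antipodally symmetric Coulomb-type energy
#' \eqn{\sum_{i<j} 1/(1 - (g_i \cdot g_j)^2)} starting from a deterministic
#' Fibonacci lattice, yielding a well-spread set of lines through the
#' origin. Deterministic for a given `n`.
#'
#' @param n number of directions
#' @param maxit optimiser iteration cap
#' @return n x 3 matrix of unit row vectors
#' @export
optimize_directions <- function(n, maxit = 2000) {
  if (n < 2) return(matrix(c(0, 0, 1), 1, 3))
  energy <- function(par) {
    X <- matrix(par, n, 3)
    X <- X / sqrt(rowSums(X^2))
    g2 <- (X %*% t(X))^2
    sum(1 / (1 - g2[upper.tri(g2)]))
  }
  o <- stats::optim(as.vector(fibonacci_sphere(n)), energy, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-14))
  X <- matrix(o$par, n, 3)
  X <- X / sqrt(rowSums(X^2))
  X * sign(X[, 3] + (X[, 3] == 0))
}
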