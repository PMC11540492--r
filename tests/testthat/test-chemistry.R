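test_that("species set carries the ten species with correct bookkeeping", {
  sp <- species_set()
  expect_equal(nrow(sp), 10)
  expect_setequal(sp$name, c("HOCl", "ClO", "ClO2", "ClO3", "O2",
                             "H", "H2", "OH", "Cl", "Na"))
  expect_true(all(sp$D298 > 0))
  expect_equal(sp$cl_atoms[match(c("HOCl", "ClO", "ClO2", "ClO3", "Cl"),
                                 sp$name)], rep(1L, 5))
  expect_equal(sum(sp$cl_atoms), 5L)
  # override mechanism
  sp2 <- species_set(D298 = c(HOCl = 2e-9))
  expect_equal(sp2$D298[sp2$name == "HOCl"], 2e-9)
  expect_error(species_set(D298 = c(XYZ = 1e-9)), "named")
})

test_that("tabulated rate constants convert to SI once, correctly", {
  p <- chem_params()
  # hand conversions: 1/min -> 1/s and L/(mol min) -> m3/(mol s)
  expect_equal(p$K0_SI, 7.75e-6)
  expect_equal(p$K1_SI, 7.5e-6)
  expect_equal(p$K2_SI, 5e-8)
  expect_equal(p$K3_SI, 1.25e-10)
})

test_that("Arrhenius correction: identity, frozen value, monotonicity", {
  expect_equal(arrhenius_adjust(4.65e-4, 19, 303.15, 303.15), 4.65e-4)
  # independently evaluated (high-precision direct formula)
  expect_equal(arrhenius_adjust(4.65e-4, 19, 303.15, 298.15),
               2.739971843643774e-4, tolerance = 1e-10)
  k <- arrhenius_adjust(7.5e-6, 15, 333.15, 310.15)
  expect_equal(k, 1.3974986153524537e-6, tolerance = 1e-10)
  expect_lt(k, 7.5e-6)
  Ts <- seq(273.15, 370.15, by = 5)
  ks <- arrhenius_adjust(1e-3, 15, 303.15, Ts)
  expect_true(all(diff(ks) > 0))
  expect_error(arrhenius_adjust(1, 15, 303.15, 120), "250")
})

test_that("equilibrium rates vanish exactly at the mass-action fixed point", {
  chem <- chem_params()
  c_eq <- equilibrated_composition(hocl = 2, pH = 4, chem = chem)
  r <- equilibrium_rates(c_eq, chem)
  expect_true(all(abs(r) < 1e-10))
  # pure neutral water: c_H = c_OH = 1e-4 mol/m3 satisfies Ka_H2O = 1e-8
  c_n <- initial_composition(7, 100)
  r_n <- equilibrium_rates(c_n, chem)
  expect_equal(unname(r_n["OH"]), 0, tolerance = 1e-12)
})

test_that("undissociated HOCl drives forward dissociation at rate ka*c", {
  chem <- chem_params()
  c <- initial_composition(5.5, 154.04)   # c_H = 3.162e-3, at water eq.
  c["HOCl"] <- 1
  r <- equilibrium_rates(c, chem)
  expect_equal(unname(r["HOCl"]), -1000)
  expect_equal(unname(r["ClO"]), 1000)
  expect_equal(unname(r["H"]), 1000)
})

test_that("degradation rates: zero without HOCl, frozen K1 value, H+ release", {
  chem <- chem_params()
  c0 <- initial_composition(5.5, 154.04)
  expect_true(all(degradation_rates(c0, 303.15, chem) == 0))
  c1 <- c0; c1["HOCl"] <- 1
  r <- degradation_rates(c1, 303.15, chem)
  # only the disproportionation 2 HOCl -> ClO2- produces chlorite here;
  # at the reference temperature its rate is K1 * c^2 = 7.5e-6
  expect_equal(unname(r["ClO2"]), 7.5e-6)
  expect_gt(unname(r["H"]), 0)
  expect_lt(unname(r["HOCl"]), 0)
})

test_that("homogeneous chemistry conserves chlorine and charge for random states", {
  chem <- chem_params()
  sp <- species_set()
  set.seed(42)
  for (rep in 1:25) {
    c <- stats::setNames(10^stats::runif(10, -6, 2), species_names())
    T <- stats::runif(1, 278, 330)
    r <- chemistry_rates(c, T, chem)
    expect_equal(sum(sp$cl_atoms * r), 0, tolerance = 1e-12 * sum(abs(r)))
    expect_equal(sum(sp$charge * r), 0, tolerance = 1e-12 * sum(abs(r)))
  }
})

test_that("initial composition: closed form, electroneutrality, validation", {
  c0 <- initial_composition(5.5, 154.04)
  expect_equal(unname(c0["H"]), 1000 * 10^-5.5, tolerance = 1e-12)
  expect_equal(unname(c0["H"]), 3.1623e-3, tolerance = 1e-4)
  expect_equal(unname(c0["OH"]), 3.1623e-6, tolerance = 1e-4)
  expect_equal(unname(c0["Na"]), 154.04)
  expect_equal(unname(c0["Cl"]), 154.0432, tolerance = 1e-6)
  sp <- species_set()
  expect_equal(sum(sp$charge * c0), 0, tolerance = 1e-10)
  # neutral water case
  cn <- initial_composition(7, 50)
  expect_equal(unname(cn["H"]), 1e-4)
  expect_equal(unname(cn["OH"]), 1e-4)
  expect_equal(unname(cn["Cl"]), 50)
  expect_error(initial_composition(0, 100), "pH0")
  expect_error(initial_composition(5, -1), "C_NaCl")
})

test_that("integrating the equilibria alone reaches the mass-action quotients", {
  chem <- chem_params()
  c0 <- initial_composition(5.5, 154.04)
  c0["HOCl"] <- 1    # undissociated spike, away from equilibrium
  c0["OH"] <- 1e-5   # water equilibrium perturbed too
  f <- function(t, y, p)
    list(equilibrium_rates(stats::setNames(y, species_names()), chem))
  sol <- deSolve::ode(y = unname(c0), times = c(0, 0.5), func = f,
                      method = "lsoda", rtol = 1e-10, atol = 1e-14)
  cf <- stats::setNames(sol[2, -1], species_names())
  q_hocl <- cf["ClO"] * cf["H"] / cf["HOCl"]
  q_h2o <- cf["OH"] * cf["H"]
  expect_equal(unname(q_hocl) / chem$Ka_HOCl, 1, tolerance = 1e-3)
  expect_equal(unname(q_h2o) / chem$Ka_H2O, 1, tolerance = 1e-3)
})
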