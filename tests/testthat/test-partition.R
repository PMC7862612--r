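# Equilibrium partitioning: mass balance, IC10 conversion, air loss.

sys_simple <- function(v_water = 1, v_pm = 0, v_lm = 0, v_pc = 0,
                       v_lc = 1e-3, v_air = 0, c_mem = 69) {
  compartment_system(v_water, v_pm, v_lm, v_pc, v_lc, v_air, c_mem)
}

test_that("compartment fractions sum to 1 and match a brute-force mass balance", {
  set.seed(61)
  for (i in 1:20) {
    chem <- chemical_profile("x", d_lipw = 10^runif(1, 0, 5),
                             d_protw = 10^runif(1, -1, 4),
                             k_aw = 10^runif(1, -6, 0))
    sys <- compartment_system(v_water = runif(1, 0.1, 1),
                              v_protein_medium = runif(1, 0, 1e-3),
                              v_lipid_medium = runif(1, 0, 1e-4),
                              v_protein_cell = runif(1, 0, 1e-3),
                              v_lipid_cell = runif(1, 1e-6, 1e-4),
                              v_air = runif(1, 0, 0.5))
    fr <- equilibrium_fractions(chem, sys)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    # conservation oracle: distribute unit mass by explicit equilibrium solve
    caps <- c(sys$v_water,
              chem$d_protw * (sys$v_protein_medium + sys$v_protein_cell),
              chem$d_lipw * (sys$v_lipid_medium + sys$v_lipid_cell),
              chem$k_aw * sys$v_air)
    cw <- 1 / sum(caps)  # free concentration for unit total mass
    expect_equal(unname(fr), cw * caps, tolerance = 1e-10)
  }
})

test_that("single-compartment and symmetric limits are exact", {
  # everything else zero -> water fraction 1
  chem0 <- chemical_profile("w", d_lipw = 1, d_protw = 0, k_aw = 0)
  fr0 <- equilibrium_fractions(chem0, sys_simple(v_lc = 1e-12))
  expect_equal(unname(fr0["water"]), 1, tolerance = 1e-9)
  # two compartments with equal capacity -> 0.5 / 0.5
  chem1 <- chemical_profile("s", d_lipw = 1000, d_protw = 0, k_aw = 0)
  fr1 <- equilibrium_fractions(chem1, sys_simple(v_water = 1, v_lc = 1e-3))
  expect_equal(unname(fr1[c("water", "lipid")]), c(0.5, 0.5))
})

test_that("IC10 conversion is consistent forward and backward", {
  set.seed(62)
  for (i in 1:20) {
    chem <- chemical_profile("x", d_lipw = 10^runif(1, 0.5, 5),
                             d_protw = 10^runif(1, -1, 4),
                             k_aw = 10^runif(1, -6, -1))
    sys <- compartment_system(v_water = runif(1, 0.1, 1),
                              v_protein_medium = runif(1, 0, 1e-3),
                              v_lipid_medium = runif(1, 0, 1e-4),
                              v_protein_cell = runif(1, 0, 1e-3),
                              v_lipid_cell = runif(1, 1e-6, 1e-4),
                              v_air = runif(1, 0, 0.5))
    pred <- predict_ic10(chem, sys)
    # back-calculate the membrane-lipid concentration at the returned IC10
    v_dose <- sys$v_water + sys$v_protein_medium + sys$v_lipid_medium +
      sys$v_protein_cell + sys$v_lipid_cell
    total_umol <- pred$ic10_uM * v_dose
    caps <- c(sys$v_water,
              chem$d_protw * (sys$v_protein_medium + sys$v_protein_cell),
              chem$d_lipw * (sys$v_lipid_medium + sys$v_lipid_cell),
              chem$k_aw * sys$v_air)
    c_w <- total_umol / sum(caps)
    c_lip_mM <- chem$d_lipw * c_w / 1000
    expect_equal(c_lip_mM, 69, tolerance = 1e-9)
  }
})

test_that("IC10 limits match the all-in-membrane and dilute-membrane forms", {
  sys <- sys_simple(v_water = 1, v_lc = 1e-3)
  v_dose <- 1 + 1e-3
  # D_lipw huge: IC10 -> c_mem_crit * V_lip / V_dose
  chem_hi <- chemical_profile("hi", d_lipw = 1e12, d_protw = 0, k_aw = 0)
  expect_equal(predict_ic10(chem_hi, sys)$ic10_uM,
               69 * 1e-3 / v_dose * 1000, tolerance = 1e-6)
  # dilute membrane: IC10 ~ (c_mem_crit / D_lipw) * V_water / V_dose
  chem_lo <- chemical_profile("lo", d_lipw = 10, d_protw = 0, k_aw = 0)
  expect_equal(predict_ic10(chem_lo, sys)$ic10_uM,
               69 / 10 * (1 + 10 * 1e-3) / v_dose * 1000, tolerance = 1e-12)
})

test_that("IC10 is monotone in the partition parameters", {
  sys <- compartment_system(v_water = 0.5, v_protein_medium = 1e-4,
                            v_lipid_medium = 1e-5, v_protein_cell = 1e-4,
                            v_lipid_cell = 1e-5, v_air = 0.2)
  ic10 <- function(dl, dp, ka) {
    predict_ic10(chemical_profile("x", dl, dp, ka), sys)$ic10_uM
  }
  dl_sweep <- vapply(10^seq(0, 5, length.out = 9), ic10, numeric(1),
                     dp = 100, ka = 1e-3)
  expect_true(all(diff(dl_sweep) <= 1e-9))          # non-increasing in D_lipw
  dp_sweep <- vapply(10^seq(-1, 4, length.out = 9), function(dp) {
    ic10(1000, dp, 1e-3)
  }, numeric(1))
  expect_true(all(diff(dp_sweep) >= 0))             # non-decreasing in D_protw
  ka_sweep <- vapply(10^seq(-6, 0, length.out = 9), function(ka) {
    ic10(1000, 100, ka)
  }, numeric(1))
  expect_true(all(diff(ka_sweep) >= 0))             # non-decreasing in K_aw V_air
})

test_that("IC10 in uM is invariant to a common volume rescaling (units round-trip)", {
  chem <- chemical_profile("x", d_lipw = 500, d_protw = 50, k_aw = 1e-3)
  sys1 <- compartment_system(0.2, 1e-4, 1e-5, 1e-4, 1e-5, 0.15)
  s <- 1e3  # litres -> millilitres, say
  sys2 <- compartment_system(0.2 * s, 1e-4 * s, 1e-5 * s, 1e-4 * s,
                             1e-5 * s, 0.15 * s)
  expect_equal(predict_ic10(chem, sys1)$ic10_uM,
               predict_ic10(chem, sys2)$ic10_uM, tolerance = 1e-12)
})

test_that("air loss fraction and the volatile flag follow the capacity ratio", {
  sys <- sys_simple(v_water = 1, v_lc = 1e-3, v_air = 0.5)
  # involatile chemical
  al0 <- air_loss_fraction(chemical_profile("x", 100, 10, k_aw = 0), sys)
  expect_equal(al0$fraction, 0)
  expect_false(al0$volatile)
  # sealed system
  al_sealed <- air_loss_fraction(chemical_profile("x", 100, 10, k_aw = 1),
                                 sys_simple(v_air = 0))
  expect_equal(al_sealed$fraction, 0)
  # constructed 90% loss: air capacity = 9 x all other capacities
  chem <- chemical_profile("volatile", d_lipw = 1, d_protw = 0, k_aw = 1)
  other <- 1 + 1 * 1e-3
  sysv <- sys_simple(v_water = 1, v_lc = 1e-3, v_air = 9 * other)
  alv <- air_loss_fraction(chem, sysv)
  expect_equal(alv$fraction, 0.9, tolerance = 1e-12)
  expect_true(alv$volatile)
  expect_true(predict_ic10(chem, sysv)$volatile)
})

test_that("degenerate partitioning inputs are rejected", {
  expect_error(chemical_profile("x", d_lipw = 0, d_protw = 1), "d_lipw")
  expect_error(compartment_system(v_water = 0), "v_water")
  expect_error(predict_ic10(chemical_profile("x", 10, 1),
                            compartment_system(1, v_lipid_cell = 0)),
               "lipid")
})
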