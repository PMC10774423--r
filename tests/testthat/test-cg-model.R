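test_that("collinear 3-bead chain below the 1-3 distance has no contacts", {
  ref <- list(resid = 1:3, coords = cbind(c(0, 3.8, 7.6), 0, 0))
  m <- build_cg_model(ref, contact_cutoff = 7)
  expect_equal(nrow(m$contacts), 0)
})

test_that("4-bead toy contacts equal the brute-force pair enumeration", {
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0))
  ref <- list(resid = 1:4, coords = coords)
  cutoff <- 5.5
  m <- build_cg_model(ref, contact_cutoff = cutoff)
  # brute force: all pairs with |i-j| >= 2 within cutoff
  expected <- list()
  for (i in 1:2) for (j in (i + 2):4) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff) {
      expected[[length(expected) + 1]] <- c(i, j)
    }
  }
  got <- unname(as.matrix(m$contacts[, c("i", "j")]))
  expect_equal(nrow(got), length(expected))
  for (k in seq_along(expected)) expect_equal(got[k, ], expected[[k]])
})

test_that("every hydrophobic-core residue touches at least one contact", {
  m <- build_cg_model(bir2_reference())
  core <- load_selections(name = "hydrophobic_core")
  expect_length(core, 11)
  for (r in core) {
    expect_gt(sum(m$contacts$i == r | m$contacts$j == r), 0)
  }
})

test_that("contact cutoff at or below the bond length is rejected", {
  ref <- list(resid = 1:3, coords = cbind(c(0, 3.8, 7.6), 0, 0))
  expect_error(build_cg_model(ref, contact_cutoff = 3.8), "exceed")
})

test_that("wild-type spec leaves the model unchanged", {
  m <- build_cg_model(bir2_reference())
  cat_ <- variant_catalog()
  m2 <- apply_variant(m, cat_[cat_$name == "WT", ])
  expect_identical(m2, m)
})

test_that("R166K removes exactly the 166-185 contact entries", {
  m <- build_cg_model(bir2_reference())
  cat_ <- variant_catalog()
  n_hb <- sum((m$contacts$i == 166 & m$contacts$j == 185) |
                (m$contacts$i == 185 & m$contacts$j == 166))
  expect_gt(n_hb, 0)
  m2 <- apply_variant(m, cat_[cat_$name == "R166K", ])
  expect_equal(nrow(m$contacts) - nrow(m2$contacts), n_hb)
})

test_that("H220Y removes every Zn-finger restraint", {
  m <- build_cg_model(bir2_reference())
  expect_equal(nrow(m$restraints), choose(4, 2))
  cat_ <- variant_catalog()
  m2 <- apply_variant(m, cat_[cat_$name == "H220Y", ])
  zn <- c(200, 203, 220, 227)
  expect_equal(sum(m2$restraints$i %in% zn | m2$restraints$j %in% zn), 0)
})

test_that("no variant increases the contact count or total well depth", {
  m <- build_cg_model(bir2_reference())
  cat_ <- variant_catalog()
  for (v in cat_$name[cat_$simulated]) {
    m2 <- apply_variant(m, cat_[cat_$name == v, ])
    expect_lte(nrow(m2$contacts), nrow(m$contacts))
    expect_lte(sum(m2$contacts$eps), sum(m$contacts$eps))
  }
})

test_that("invalid variant specs are rejected", {
  m <- build_cg_model(bir2_reference())
  bad <- tibble::tibble(name = "X1Y", mechanism = "melt", resid = 170L)
  expect_error(apply_variant(m, bad), "unknown mechanism")
  bad2 <- tibble::tibble(name = "A999B", mechanism = "core_collapse",
                         resid = 999L)
  expect_error(apply_variant(m, bad2), "not present")
})

test_that("catalog lists WT plus eight default variants, names unique", {
  cat_ <- variant_catalog()
  expect_equal(sum(cat_$simulated), 9)
  expect_false(anyDuplicated(cat_$name) > 0)
  expect_setequal(cat_$name[cat_$simulated],
                  c("WT", "R166I", "R166K", "W173G", "G188E", "L189P",
                    "V198M", "L207P", "H220Y"))
})
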