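test_that("phantom generation is deterministic and honours the spec", {
  sp <- phantom_spec(shape = c(12L, 48L, 48L), n_lesions = 3L,
                     groups = c("5-10", "21-50", ">100"), seed = 9L)
  ph1 <- generate_phantom(sp)
  ph2 <- generate_phantom(sp)
  expect_identical(ph1$stack$data, ph2$stack$data)
  expect_identical(ph1$mask, ph2$mask)
  # component count and sizes match the generator's table exactly
  cc <- connected_components_6(ph1$mask)
  expect_equal(cc$n_components, 3L)
  expect_equal(sort(cc$sizes), sort(ph1$sizes$size_voxels))
  bounds <- list("5-10" = c(5, 10), "21-50" = c(21, 50), ">100" = c(101, Inf))
  for (i in 1:3) {
    b <- bounds[[ph1$sizes$group[i]]]
    expect_gte(ph1$sizes$size_voxels[i], b[1])
    expect_lte(ph1$sizes$size_voxels[i], b[2])
  }
})

test_that("a lesion-free phantom still has a brain", {
  ph <- generate_phantom(phantom_spec(shape = c(10L, 40L, 40L),
                                      n_lesions = 0L, seed = 2L))
  expect_equal(sum(ph$mask), 0)
  i_wm <- match("p_wm", ph$stack$channels)
  expect_gt(sum(ph$stack$data[i_wm, , , ] > 0.5), 100)
})

test_that("contrast behaviour: post-contrast enhancement and ring cores", {
  sp <- phantom_spec(shape = c(14L, 56L, 56L), n_lesions = 2L,
                     groups = c("51-100", ">100"), ring_fraction = 1,
                     noise_sd = 0, contrast_jitter = 0, seed = 31L)
  ph <- generate_phantom(sp)
  st <- ph$stack
  ch <- function(nm) array(st$data[match(nm, st$channels), , , ],
                           dim(st$data)[2:4])
  inside <- ph$mask
  # enhancing voxels: hyperintense post vs pre contrast (partial-volume
  # smoothing dilutes thin rings, so the margin is modest)
  expect_gt(mean(ch("t1_post")[inside]) - mean(ch("t1_pre")[inside]), 0.15)
  # ovoid lesions enhance strongly
  sp_ov <- phantom_spec(shape = c(14L, 56L, 56L), n_lesions = 2L,
                        groups = c("51-100", ">100"), ring_fraction = 0,
                        noise_sd = 0, contrast_jitter = 0, seed = 31L)
  ph_ov <- generate_phantom(sp_ov)
  st_ov <- ph_ov$stack
  post_ov <- array(st_ov$data[match("t1_post", st_ov$channels), , , ],
                   dim(st_ov$data)[2:4])
  pre_ov <- array(st_ov$data[match("t1_pre", st_ov$channels), , , ],
                  dim(st_ov$data)[2:4])
  expect_gt(mean(post_ov[ph_ov$mask]) - mean(pre_ov[ph_ov$mask]), 0.35)
  # FLAIR/T2 hyperintense at lesions relative to white matter
  wm <- ch("p_wm") > 0.9 & !dilate6(dilate6(inside))
  expect_gt(mean(ch("flair")[inside]), mean(ch("flair")[wm]))
  expect_gt(mean(ch("t2")[inside]), mean(ch("t2")[wm]))
  expect_true(all(ph$sizes$type == "ring"))
  # ring core (interior holes of the mask) darker than the rim on T1 post
  core <- dilate6(inside) & !inside & ch("p_wm") > 0.5
  expect_gt(mean(ch("t1_post")[inside]), mean(ch("t1_post")[core]))
})

test_that("tissue probability channels are proper and sum to at most 1", {
  ph <- generate_phantom(phantom_spec(shape = c(10L, 40L, 40L),
                                      n_lesions = 1L, groups = "21-50",
                                      seed = 6L))
  st <- ph$stack
  probs <- lapply(c("p_gm", "p_wm", "p_csf", "p_vent", "p_lesion"),
                  function(nm) st$data[match(nm, st$channels), , , ])
  for (p in probs) expect_true(all(p >= 0 & p <= 1))
  tissue_sum <- probs[[1]] + probs[[2]] + probs[[3]]
  expect_lte(max(tissue_sum), 1 + 1e-9)
})

test_that("post-contrast lesion contrast is monotone in the boost", {
  cnr <- vapply(c(0.2, 0.5, 0.9), function(boost) {
    sp <- phantom_spec(shape = c(12L, 48L, 48L), n_lesions = 2L,
                       groups = "51-100", lesion_boost = boost,
                       ring_fraction = 0, seed = 13L)
    ph <- generate_phantom(sp)
    i_post <- match("t1_post", ph$stack$channels)
    post <- array(ph$stack$data[i_post, , , ], dim(ph$stack$data)[2:4])
    wm <- ph$stack$data[match("p_wm", ph$stack$channels), , , ] > 0.9 &
      !dilate6(ph$mask)
    (mean(post[ph$mask]) - mean(post[wm])) / sd(post[wm])
  }, numeric(1))
  expect_true(all(diff(cnr) > 0))
})

test_that("infeasible lesion placement fails loudly", {
  sp <- phantom_spec(shape = c(6L, 16L, 16L), n_lesions = 8L,
                     groups = ">100", seed = 1L)
  expect_error(generate_phantom(sp), "infeasible")
})

test_that("cohort prevalence and count categories behave", {
  tmpl <- phantom_spec(shape = c(6L, 24L, 24L), n_lesions = 2L,
                       groups = "5-10", n_distractors = 0L)
  coh0 <- generate_cohort(6, 0, tmpl, seed = 2L)
  expect_true(all(coh0$manifest$category == "0"))
  coh1 <- generate_cohort(5, 1, phantom_spec(shape = c(6L, 24L, 24L),
                                             n_lesions = 2L,
                                             groups = "5-10",
                                             n_distractors = 0L),
                          seed = 3L)
  expect_true(all(coh1$manifest$n_lesions >= 1))
  expect_true(all(coh1$manifest$category %in% c("1", ">=2")))
  # categories always consistent with the realized masks
  for (i in seq_along(coh1$phantoms)) {
    cc <- connected_components_6(coh1$phantoms[[i]]$mask)
    expect_equal(categorize_count(cc$n_components),
                 coh1$manifest$category[i])
  }
})

test_that("observed cohort prevalence sits in the binomial interval", {
  # interval oracle: central 95% binomial bounds at the clinical 6.5% rate
  n <- 200; p <- 0.065
  lo <- qbinom(0.025, n, p); hi <- qbinom(0.975, n, p)
  tmpl <- phantom_spec(shape = c(4L, 24L, 24L), n_lesions = 1L,
                       groups = "5-10", n_distractors = 0L)
  coh <- generate_cohort(n, p, tmpl, seed = 11L)
  k <- sum(coh$manifest$n_lesions >= 1)
  expect_gte(k, lo)
  expect_lte(k, hi)
})
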