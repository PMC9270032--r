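# build a feature-RBF kernel whose classes are separated by `gap`
toy_gram <- function(n_animals_per_class = 5, items_per_animal = 4, gap = 10,
                     noise = 0.5, bandwidth = 5, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("F%02d", seq_len(n_animals_per_class)),
           sprintf("M%02d", seq_len(n_animals_per_class)))
  cls <- rep(c("female", "male"), each = n_animals_per_class)
  feats <- NULL
  gid <- character()
  labels <- character()
  for (i in seq_along(ids)) {
    centre <- if (cls[i] == "male") gap else 0
    animal_shift <- rnorm(1, 0, noise)
    f <- cbind(centre + animal_shift + rnorm(items_per_animal, 0, noise / 2),
               rnorm(items_per_animal, 0, noise))
    feats <- rbind(feats, f)
    gid <- c(gid, rep(ids[i], items_per_animal))
    labels <- c(labels, rep(cls[i], items_per_animal))
  }
  list(gram = rbf_feature_gram(feats, bandwidth = bandwidth, group_ids = gid),
       labels = labels)
}

test_that("group splits have the published sizes and never leak animals", {
  animals <- data.frame(
    id = c(sprintf("F%02d", 1:16), sprintf("M%02d", 1:15)),
    class = rep(c("female", "male"), c(16, 15))
  )
  plans <- make_group_splits(animals, n_train_per_class = 6, n_splits = 25,
                             seed = 3)
  for (p in plans) {
    expect_length(p$train_animals, 12)
    expect_length(p$test_animals, 19)
    expect_length(intersect(p$train_animals, p$test_animals), 0)
    expect_equal(sum(startsWith(p$train_animals, "F")), 6)
    expect_equal(sum(startsWith(p$train_animals, "M")), 6)
  }
  # with 100 subsamples per animal: 1200 training and 1900 testing items
  expect_equal(length(plans[[1]]$train_animals) * 100, 1200)
  expect_equal(length(plans[[1]]$test_animals) * 100, 1900)

  expect_identical(
    make_group_splits(animals, 6, 5, seed = 9)[[5]]$train_animals,
    make_group_splits(animals, 6, 5, seed = 9)[[5]]$train_animals
  )
  expect_length(make_group_splits(animals, 6, 0, seed = 1), 0)
  few <- data.frame(id = c("a", "b", "c"), class = c("f", "f", "m"))
  expect_error(make_group_splits(few, 1), "need more than")
})

test_that("item order within an animal never changes split membership", {
  toy <- toy_gram(seed = 5)
  plan <- make_group_splits(
    data.frame(id = unique(toy$gram$group_ids),
               class = toy$labels[!duplicated(toy$gram$group_ids)]),
    n_train_per_class = 3, n_splits = 1, seed = 11
  )[[1]]
  membership <- toy$gram$group_ids %in% plan$train_animals
  perm <- sample(length(membership))
  membership_perm <- (toy$gram$group_ids[perm] %in% plan$train_animals)
  expect_equal(membership_perm, membership[perm])
  # all items of an animal fall on one side
  split_by_animal <- tapply(membership, toy$gram$group_ids, function(v) length(unique(v)))
  expect_true(all(split_by_animal == 1))
})

test_that("pearson matches hand-computed values and handles degeneracy", {
  expect_equal(pearson(c(1, 5, 2), c(1, 5, 2)), 1)
  expect_equal(pearson(c(1, 5, 2), -c(1, 5, 2)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84), tolerance = 1e-12)
  expect_warning(r <- pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("a separable kernel gives rho_true = 1 and label flips negate rho", {
  toy <- toy_gram(gap = 20, noise = 0.3, seed = 7)
  animals <- unique(toy$gram$group_ids)
  plan <- make_group_splits(
    data.frame(id = animals, class = toy$labels[!duplicated(toy$gram$group_ids)]),
    n_train_per_class = 3, n_splits = 1, seed = 2
  )[[1]]
  r <- run_split(toy$gram, toy$labels, plan, c = 10, control_seed = 5)
  expect_equal(r$rho_true, 1)

  # flipping all test labels negates the correlation
  y <- ifelse(toy$labels == "male", 1, -1)
  test_idx <- which(toy$gram$group_ids %in% plan$test_animals)
  pred <- rep(c(-1, 1), length.out = length(test_idx))
  expect_equal(pearson(pred, y[test_idx]), -pearson(pred, -y[test_idx]))
})

test_that("experiments detect a signal kernel and stay at chance on noise", {
  toy <- toy_gram(gap = 20, noise = 0.3, seed = 9)
  cfg <- experiment_config(n_splits = 60, train_animals_per_class = 3,
                           master_seed = 17)
  exp_sig <- run_experiment(toy$gram, toy$labels, cfg)
  expect_lt(exp_sig$overlap_fraction, 0.05)
  expect_equal(nrow(exp_sig$per_split), 60)
  expect_true(all(abs(exp_sig$per_split$rho_true) <= 1 + 1e-12))

  null <- toy_gram(gap = 0, noise = 0.5, seed = 10)
  exp_null <- run_experiment(null$gram, null$labels, cfg)
  expect_gt(exp_null$overlap_fraction, 0.20)
  expect_lt(exp_null$overlap_fraction, 0.80)

  # determinism under the master seed
  exp_rep <- run_experiment(toy$gram, toy$labels, cfg)
  expect_identical(exp_sig$per_split, exp_rep$per_split)

  one <- run_experiment(toy$gram, toy$labels,
                        experiment_config(n_splits = 1,
                                          train_animals_per_class = 3,
                                          master_seed = 1))
  expect_true(one$overlap_fraction %in% c(0, 1))
})

test_that("the hyperparameter grid is deterministic and finds the signal", {
  toy <- toy_gram(gap = 15, noise = 0.4, seed = 13)
  builder <- function(sigma) toy$gram # bandwidth fixed; c varies
  grid <- hyperparameter_grid(builder, toy$labels, c_values = c(0.1, 1, 10),
                              sigma_values = c(1, 1), n_train_per_class = 3,
                              seed = 21)
  expect_equal(nrow(grid), 6)
  # duplicated sigma values give identical rows
  expect_equal(grid$rho_test[grid$sigma == 1][1:3],
               grid$rho_test[grid$sigma == 1][4:6])
  expect_gte(max(grid$rho_test), 0.8)

  single <- hyperparameter_grid(builder, toy$labels, 10, 1,
                                n_train_per_class = 3, seed = 21)
  expect_equal(nrow(single), 1)
  expect_error(hyperparameter_grid(builder, toy$labels, numeric(), 1),
               "non-empty")
})
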