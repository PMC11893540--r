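# Hamming periodogram, linear-scale averaging, PSD40 extraction and
# neighbour-band SNR.

test_that("a pure 40 Hz tone peaks exactly at the 40 Hz bin", {
  fs <- 200
  t <- seq_len(30 * fs) / fs
  spec <- epoch_psd(sin(2 * pi * 40 * t), fs, expected_seconds = 30)
  expect_equal(spec$df, 1 / 30)
  i40 <- which.max(spec$power_db)
  expect_equal(spec$frequencies[i40], 40)
  expect_equal(extract_psd40(spec), max(spec$power_db))
})

test_that("epoch length is validated and zero epochs hit the dB floor", {
  expect_error(epoch_psd(rnorm(100), 200, expected_seconds = 30),
               "expected 6000")
  expect_message(spec <- epoch_psd(rep(0, 200), 200),
                 "floored")
  expect_true(all(spec$power_db == -400))
})

test_that("the periodogram matches a brute-force windowed DFT", {
  set.seed(4)
  fs <- 1000
  x <- rnorm(fs)  # 1 s toy epoch
  spec <- epoch_psd(x, fs)
  oracle <- dft_psd_oracle(x, fs)
  expect_equal(spec$frequencies, oracle$frequencies)
  lin <- 10^(spec$power_db / 10) * 1e12   # back to uV^2/Hz
  expect_equal(lin, oracle$power, tolerance = 1e-10)
  # a 1 Hz grid from a 1 s window still contains the 40 Hz bin
  expect_equal(spec$df, 1)
  expect_silent(extract_psd40(spec))
})

test_that("Parseval holds: sum(PSD) * df equals the normalised windowed energy", {
  set.seed(5)
  for (fs in c(200, 1000)) {
    x <- rnorm(2 * fs) * 10
    spec <- epoch_psd(x, fs)
    lin <- 10^(spec$power_db / 10) * 1e12
    w <- signal::hamming(length(x))
    expect_equal(sum(lin) * spec$df, sum((x * w)^2) / sum(w^2) *
                   length(x) / length(x), tolerance = 1e-8)
  }
})

test_that("scaling a signal by c raises PSD40 by exactly 20 log10(c)", {
  set.seed(6)
  fs <- 200
  x <- rnorm(30 * fs) + sin(2 * pi * 40 * seq_len(30 * fs) / fs)
  p1 <- extract_psd40(epoch_psd(x, fs))
  p3 <- extract_psd40(epoch_psd(3 * x, fs))
  expect_equal(p3 - p1, 20 * log10(3), tolerance = 1e-9)
})

test_that("averaging works on the linear scale", {
  set.seed(7)
  fs <- 200
  s1 <- epoch_psd(rnorm(30 * fs), fs)
  # idempotence
  avg_same <- average_psd(list(s1, s1, s1))
  expect_equal(avg_same$power_db, s1$power_db)
  expect_equal(avg_same$n_epochs_averaged, 3L)
  # powers p and 3p average to 2p at every bin
  s3 <- s1; s3$power_db <- s1$power_db + 10 * log10(3)
  avg <- average_psd(list(s1, s3))
  expect_equal(avg$power_db, s1$power_db + 10 * log10(2), tolerance = 1e-9)
  # mismatched grids are refused
  s_short <- epoch_psd(rnorm(10 * fs), fs)
  expect_error(average_psd(list(s1, s_short)), "grids")
})

test_that("averaging n spectra shrinks the bin variance about n-fold", {
  set.seed(8)
  fs <- 200
  spectra <- lapply(1:100, function(i) epoch_psd(rnorm(30 * fs), fs))
  lin <- function(s) 10^(s$power_db / 10)
  # across-bin variance (thousands of bins) as a cheap variance estimate
  sel <- 3:2800   # skip DC-adjacent and Nyquist-adjacent bins
  v1 <- mean(vapply(spectra[1:5], function(s) var(lin(s)[sel]), 0))
  v100 <- var(lin(average_psd(spectra))[sel])
  expect_equal(v100 / v1, 1 / 100, tolerance = 0.5)
})

test_that("extract_psd40 refuses grids without an exact 40 Hz bin", {
  spec <- epoch_psd(rnorm(600), 200)  # 3 s window, df = 1/3 Hz
  expect_silent(extract_psd40(spec))  # 40 = 120/3 is on this grid
  spec$frequencies <- spec$frequencies + 0.1
  expect_error(extract_psd40(spec), "no bin at exactly 40")
  spec2 <- epoch_psd(rnorm(30 * 200), 200)
  spec2$power_db[which(abs(spec2$frequencies - 40) < 1e-9)] <- -120
  expect_equal(extract_psd40(spec2), -120)
})

test_that("neighbour-band SNR behaves like a linear power ratio", {
  fs <- 200; n <- 30 * fs
  flat <- structure(list(frequencies = (0:(n / 2)) / 30,
                         power_db = rep(-130, n / 2 + 1),
                         n_epochs_averaged = 1L, df = 1 / 30),
                    class = "spectrum40")
  expect_equal(psd_snr(flat), 1)
  tenx <- flat
  i40 <- which(abs(tenx$frequencies - 40) < 1e-9)
  tenx$power_db[i40] <- -130 + 10 * log10(10)
  expect_equal(psd_snr(tenx), 10)
  # neighbour selection: inclusive bounds, 40 Hz bin itself excluded
  nb <- abs(flat$frequencies - 39.5) < 1e-9
  flat$power_db[nb] <- -100
  expect_gt(psd_snr(flat), 0)
  expect_error(psd_snr(flat, bands = rbind(c(500, 600))), "neighbour")
})

test_that("bin-level PSD40 summarises surviving epochs only", {
  es <- toy_epoch_set(n = 6, fs = 200)
  es$meta$rejected[5:6] <- TRUE
  res <- bin_psd40(es)
  expect_s3_class(res, "psd40_result")
  expect_equal(res$n_epochs, 4)
  expect_equal(res$stage, "N3")
  es$meta$rejected[] <- TRUE
  expect_error(bin_psd40(es), "no surviving")
})
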