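## Shared fixtures. Expensive simulations are memoised in a session-level
## environment so the acceptance-style end-to-end checks can share one
## synthetic head and one processed simulation.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
    get(key, envir = .fixtures)
}

## Default-condition synthetic head (the study grid).
getHead128 <- function() memo("head128", generateHead(headSpec(seed = 1L)))

getHeadSmall <- function() memo("head64",
    generateHead(headSpec(shape = c(64, 64, 64), seed = 1L)))

getChiLocal128 <- function() memo("chiL128",
    composeHeadChi(getHead128(), mode = "local"))

getChiWhole128 <- function() memo("chiW128",
    composeHeadChi(getHead128(), mode = "whole_head"))

## Noiseless local-field simulation at native resolution, challenge protocol.
getLocalSimNative <- function() memo("simLocalNative",
    simulateProtocol(getHead128(), getChiLocal128(), protocolPreset("challenge")))

getLocalProcNative <- function() memo("procLocalNative",
    processEchoes(getLocalSimNative()$series, getHead128()$masks$brain))

## A digitised sphere susceptibility volume (Delta chi in ppm).
sphereChi <- function(n = 96, radius = 12, dchi = 1) {
    ax <- seq_len(n) - (n + 1) / 2
    x <- array(ax, dim = c(n, n, n))
    y <- aperm(x, c(2, 1, 3))
    z <- aperm(x, c(3, 2, 1))
    r2 <- x^2 + y^2 + z^2
    chi <- array(0, dim = c(n, n, n))
    chi[r2 <= radius^2] <- dchi
    list(chi = methods::new("SusceptibilityVolume", chi = chi,
                            mode = "whole_head",
                            brainMask = array(r2 <= radius^2, dim = dim(chi)),
                            spacing = c(1, 1, 1)),
         r2 = r2, x = x, y = y, z = z, radius = radius, dchi = dchi)
}

## Independent scalar implementation of the steady-state spoiled-GRE signal,
## used as the oracle for the vectorised simulator.
scalarGRE <- function(M0, R1, R2star, TR, TE, alphaDeg, phi0, dwRad) {
    a <- alphaDeg * pi / 180
    E1 <- exp(-TR * R1)
    mag <- M0 * sin(a) * (1 - E1) / (1 - cos(a) * E1) * exp(-TE * R2star)
    complex(modulus = mag, argument = phi0 + TE * dwRad)
}
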