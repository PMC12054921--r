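Package: mieinvert
Title: Inverse Mie Scattering Reconstruction of Infrared Optical Constants
Version: 0.1.0
Authors@R:
    person("Ravn", "Eriksen", email = "ravn.eriksen@posteo.net", role = c("aut", "cre"))
Description: Reconstructs the frequency-dependent complex permittivity
    (equivalently the complex refractive index) of a homogeneous absorbing
    sphere from its mid-infrared extinction-efficiency spectrum.  The
    dielectric response is modelled as a superposition of Kramers-Kronig
    consistent Lorentz oscillator bands; a Lorenz-Mie forward model maps any
    candidate permittivity to the extinction efficiency Qext of the sphere,
    and a bounded Levenberg-Marquardt fit inverts the map by nonlinear least
    squares.  Includes a direct permittivity-fitting mode for basis
    validation, an anti-symmetrized-Lorentzian comparison basis, a numerical
    Kramers-Kronig consistency check, a synthetic polymer-like material
    generator, delimited-text readers and writers for dispersion and
    extinction tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
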