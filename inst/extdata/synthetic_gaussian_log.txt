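 Entering Gaussian System, Link 0
 This is a SYNTHETIC log excerpt bundled for testing the free-energy
 extraction helper; it was written by hand and corresponds to no real
 calculation.
 ...
 Zero-point correction=                           0.310926 (Hartree/Particle)
 Thermal correction to Energy=                    0.327680
 Thermal correction to Enthalpy=                  0.328624
 Thermal correction to Gibbs Free Energy=         0.258063
 Sum of electronic and zero-point Energies=          -1116.474237
 Sum of electronic and thermal Energies=             -1116.457483
 Sum of electronic and thermal Enthalpies=           -1116.456539
 Sum of electronic and thermal Free Energies=        -1116.527100
 ...
 Normal termination.
 Entering Gaussian System, Link 0
 Second SYNTHETIC block (protonated species).
 Sum of electronic and thermal Free Energies=        -1116.989541
 Normal termination.
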