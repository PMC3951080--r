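# Default 4-bin Hounsfield-unit conversion table.
# density(HU) = a + b * HU  (g/cm^3), bins (hu_low, hu_high], boundary HU
# assigned to the lower bin.  Ramps are continuous at the boundaries and
# anchored at rho(0) = 1.00 (water-equivalent soft tissue) and air at
# -1000 HU.  A finer stoichiometric calibration can be supplied as a user
# table in this same format.
#
# hu_low  hu_high  material     a          b
 -1100    -950     air          0.0012048  0
 -950     -200     lung         1.0        0.001
 -200      120     soft_tissue  1.0        0.001
  120     3000     bone         1.04896    0.000592
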