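# Built-in material library.
#
# Provenance: elemental compositions are standard reference values —
# water and air from the ICRU-37 / NIST material tables; Gammex-type
# solid water from the vendor elemental analysis (8.09% H, 67.17% C,
# 2.41% N, 19.88% O, 0.14% Cl, 2.31% Ca), density 1.04 g/cm^3
# (vendor-standard, overridable); PMMA is C5H8O2 at 1.19 g/cm^3;
# tissue compositions follow the ICRU-44 adult reference tissues, with
# inflated lung as soft tissue at 0.30 g/cm^3.  Mean excitation
# energies are stated where a standard value differs from the Bragg
# additivity rule (water 75 eV, air 85.7 eV, PMMA 74 eV); otherwise
# they are derived from the elemental I values.
#
# Format: records of
#   material <name>
#   density <g/cm3>
#   I <eV>              (optional)
#   elements <sym> <w> <sym> <w> ...
#   end

material water
density 1.000
I 75.0
elements H 0.1119 O 0.8881
end

material air
density 0.0012048
I 85.7
elements C 0.000124 N 0.755267 O 0.231781 Ar 0.012828
end

material solid_water
density 1.04
elements H 0.0809 C 0.6717 N 0.0241 O 0.1988 Cl 0.0014 Ca 0.0231
end

material PMMA
density 1.19
I 74.0
elements H 0.080538 C 0.599848 O 0.319614
end

material soft_tissue
density 1.00
elements H 0.102 C 0.143 N 0.034 O 0.708 Na 0.002 P 0.003 S 0.003 Cl 0.002 K 0.003
end

material adipose
density 0.95
elements H 0.114 C 0.598 N 0.007 O 0.278 Na 0.001 S 0.001 Cl 0.001
end

material muscle
density 1.05
elements H 0.102 C 0.143 N 0.034 O 0.710 Na 0.001 P 0.002 S 0.003 Cl 0.001 K 0.004
end

material lung
density 0.30
elements H 0.102 C 0.143 N 0.034 O 0.708 Na 0.002 P 0.003 S 0.003 Cl 0.002 K 0.003
end

material bone
density 1.85
elements H 0.034 C 0.155 N 0.042 O 0.435 Na 0.001 Mg 0.002 P 0.103 S 0.003 Ca 0.225
end
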