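input APC
input ECM
input IL2
input IL2RB
input IL10
input IL10RA
input IL4
input GalphaQ_L
input Galpha12_13_L
input CAV1_Activator
input GalphaS_L
input CGC
input GP130
input IFNB
input IFNG
input IFNGR1
input IFNGR2
input IL10RB
input IL12
input IL15
input IL15RA
input IL18
input IL21
input IL22
input IL23
input IL27
input IL27RA
input IL6
input IL6RA
input IL9
input TGFB
TCR = APC
CD28 = APC
Integrin = ECM
CAV1 = CAV1_Activator | TCR | Integrin
LCK = TCR & CAV1
FYN = TCR & CAV1
TCRzeta = TCR & (LCK | FYN)
ZAP70 = TCRzeta
LAT = ZAP70
GRB2 = LAT
SHC1 = LAT
SOS = GRB2 | SHC1
SHP2 = LAT & CAV1
CD26 = !CAV1
CARMA1 = LAT & CAV1
BCL10 = TCR & !CAV1
MALT1 = BCL10 | CARMA1
IL10R = IL10 & IL10RA
NFKB = MALT1 & !IL10R
NOS2A = NFKB & CAV1
IL2R = IL2 & IL2RB
RAS = SOS | IL2R
KSR1 = CAV1
RAF = RAS & KSR1
MEK = RAF & Integrin
ERK = MEK
MAPK = ERK
PI3K = CD28 | GalphaQ_L
AKT = PI3K
RAC1 = Integrin | !CAV1
Cdc42 = Galpha12_13_L
ARP2_3 = RAC1 | Cdc42
F_actin = ARP2_3 & Integrin
GATA3 = IL4 | !CAV1
Proliferation = ERK
Survival = AKT | IL2R
Cytoskeletal_Rearrangement = F_actin
STAT_Milieu = IFNB | IFNG | IFNGR1 | IFNGR2 | IL12 | IL15 | IL15RA | IL18 | IL21 | IL22 | IL23
Accessory_Milieu = GalphaS_L | CGC | GP130 | IL10RB | IL27 | IL27RA | IL6 | IL6RA | IL9 | TGFB
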