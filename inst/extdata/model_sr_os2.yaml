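# Six-latent path model for the mushroom-crop rotation experiment.
# The two required pathways are:
#   biological:      Rotation -> SoilProperties -> MicrobialCommunity -> EnzymeRatios
#   physicochemical: Rotation -> Micronutrients -> EnzymeActivity -> EnzymeRatios
# Rotation is encoded as a single ordinal indicator (stage 1-4).
latents:
  - name: Rotation
    indicators: [rotation]
  - name: SoilProperties
    indicators: [SOC, TN, AP, pH]
  - name: Micronutrients
    indicators: [Mg, Fe, Mn, Cu, Zn]
  - name: MicrobialCommunity
    indicators: [bact_chao1, bact_simpson, fung_chao1, fung_simpson]
  - name: EnzymeActivity
    indicators: [BG, NAG, PPO]
  - name: EnzymeRatios
    indicators: [ratio_cn, ratio_cppo, ratio_cp, ratio_nagl]
paths:
  - {from: Rotation, to: SoilProperties}
  - {from: Rotation, to: Micronutrients}
  - {from: SoilProperties, to: MicrobialCommunity}
  - {from: Micronutrients, to: EnzymeActivity}
  - {from: MicrobialCommunity, to: EnzymeRatios}
  - {from: EnzymeActivity, to: EnzymeRatios}
scheme: path
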