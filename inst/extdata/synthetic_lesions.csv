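id,species,setting,current_uA,duration_s,geometry,radius_mm,height_mm,damage_type
EX01,sheep,ex_vivo,180,15,cone,0.01239,,cavitation
EX02,pig,ex_vivo,180,22,cone,0.01596,,cavitation
EX03,sheep,ex_vivo,180,29,cone,0.01875,,cavitation
EX04,pig,ex_vivo,180,35,cone,0.02617,,cavitation
EX05,sheep,ex_vivo,180,42,cone,0.03037,,cavitation
EX06,pig,ex_vivo,180,49,cone,0.03545,,cavitation
EX07,sheep,ex_vivo,180,56,cone,0.04679,,cavitation
EX08,pig,ex_vivo,180,63,cone,0.05857,,cavitation
EX09,sheep,ex_vivo,180,70,cone,0.07183,,cavitation
EX10,pig,ex_vivo,180,76,cone,0.08497,,cavitation
EX11,sheep,ex_vivo,180,83,cone,0.115,,cavitation
EX12,pig,ex_vivo,180,90,cone,0.1345,,cavitation
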