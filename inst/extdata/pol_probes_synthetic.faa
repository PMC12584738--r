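>GammaA_POL synthetic_probe genus=Gamma
FFFLGSMMEGYLQFQEVKLISQSMYGSQVSARLTMVAFSEWSVLSSRTEYIWSVNPQPATIMAYAFQTTP
KQGAEQPSRNQDRRKTQVWTRYQSFFNLNMLWEMVQAYDVNQQFSKKYNGNSGSPPWQDFVIGDTVMAEW
METQSFRIEYVAIYFVDYLTSIQEWPVPAVAKAQWNPGFFYDGQGFKFQYYPSDIRVFKWKFDQFNEYDN
WAEFEDKYWAVMKKMRPIFSYRAATTMNDDGVELYFIRPWELPRDNIKMNTFNWDTTDRQTWYRGQWGMG
MVFVWRRQGWRNDEEDTFTIEYRMRSDILTEVDGPEDPYSIWAGVAIKLWWVETDMYNWGYFSQTRVWKF
GAGFYATVKGKINFEIPMVKRNGVEEGMRFFTVGVVDSAWWQWPTWVMDINWAIRIVLLMGNFIEDKSGI
KRFNTRSGGSSNGVIGKKARFSVDPYANTQNKKQIKGTQQYTLPVYIVMSYGYGDSDYLVGTMGISIKEP
GWALAWATTFEWQFMVPFGQGINQSEWTRGQRKDVSIWIFARRGIVVGWGEEPIWINRRQMGTVMDNLEF
LFWGPMGIGYKKERSPGYVIIETGQSGMTKKFVDNKVNYRMDTELFTNEKPTQDGMIWFNVAPPGRRNAL
AGIPQQVYNQNRGGFMEVMWMWDVAEEVLRSKTPALWEEFSKLAWQPPMGLYYYQYGVYTLRDKVFVANT
IQGSALETVNAFDTIGLMWF
>GammaB_POL synthetic_probe genus=Gamma
WEKFYEIQPFPTIFETEWGWPDFMVYFTRTDSTEIMPNTIIAAQAETEYWLIRKPERARRTEYFTMGNFR
TWTYRDKSRLVPWPINEQIMPSRDGDYYSMWKKRVEWTIRAKLWISPDTDFKQVAAFYWGFPFDTNTQTE
WRFYEKGWGQWGKSQQLDREFMWRPYPFFREWKDARADSWPLKADRRMPSIAYGPATFGEAQPMTMYRWK
KELDYMQAIDDWPWFWAKNNLEDITFGMATRNKYGDTQVVMIKTGVFGYIAFDGRFWAIQQQVRYTPDPM
PYVIGVLITDREMQPFEGIYDKRTYAGWNAGVGNDPAYGGPFQNEVKMGSVWTAEFPSIQPYAMYQWYPV
LQRFMQDGLPWTRQQGKQRPISFALAQSEMIYRPIIRTWYMSNNMYKKWVLDWQAPRYIEMALDPPPQTK
VYGEQDQYSYFYYQYWRKSWWNKRGAWGLNEWLNLYSKQLYFNIMSKKVSMESLFAGREWPRVKDKWAER
YQATQWMRLSSYDKVLMAQTQWMVDVPATPRNWIQNRLPYANENMRKFEEISQTKYIVWLFIVWKLNKAQ
YPQRRPAETAMWPWAFFNKYNELIDGFQDRAEQVDITDAYVPYWSQGNPKFDQDNESPMFRVWGDANANN
QDIMKNLYTNQTWFFRLYMDMADGEVKRTNGIVDDLMMFRLKTKETTADQNKQEKEKSTDIAQDSFTFAT
IQPWKMVEWDPRSTSGMARP
>BetaA_POL synthetic_probe genus=Beta
DLNEVTFKQRRPARTKGRESVLQTIVKMPISYETNAQASNNKAPQIEREFTKPYYERPLGTGYADNNGPV
VLKNAPYLDKEPSFGEDLNEINIYLGAQQKNGDPDEKLGMTQDVQVYIRQMPTYARNVLSTMIWENAPIA
NGQKVNSMQRIRAMVKTLVSEVARLRKDPNPRVSRSVWIFYNFMIYTYKMNSPGGNGYYIVYEQYFWVFQ
EYKGVYAQEYIYARLKMNVFEPEKDPSIWGDVGQTPMFKADVTLPWLIQMGSTLMYYAVRWSFVEKDRDN
NMALEMGRKMFLGIPNEDASQLASFGASVPEDAYMQYSKNNFQDTWEGLPIVPKIFNIKLTIESTRKPSW
DDKPPKGSRPPLREDFVANGAPQYRVMSNWFNEIYFERFFIMADQQEYMDKWRPPDVASGNVLNSNAFWL
SFTEFGPGMYAPGYGYVKNVILEIQQPWQKRGKGANIGAMLTPQWSNAGGIWDEMEWPVARITNKPKDMV
PMAGLRSSSDQTPQDFNKWNLITRMWADTYGWYINFMNPEKVDPETEYFFAQPIRDTVPDYTTWRRMEKQ
ERAYWVMPTVYLKVYKVTNEYAKLARVEKPFDPWVQKMDRAFDNGFWSYNDQMVTPTFNSYEAKMNGGYV
YGILWDVPDVADMTSALTIIPRMQGFRKRDLLFIMTDKNIERNWEVNSQNEEMPQNGMATTEINEFVGPP
IATKLTEGWMSVRVIAYPRN
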