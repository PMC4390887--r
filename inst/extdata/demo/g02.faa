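>p1
MRIEEVPFECWQTVGGCYDCGLIFATHEPTKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFFSY
LLAWTQQRGRMFSTTVCGGGYRCLNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATAQISDFPNA
WFRGPLH
>p2
KKDVRRYSAGMNYPFVRCGAQSTMVCLEYRHTFSVKMLLKWKMWELTNGRKLVHQNWLFCDCQSEGYYMA
QAEPGNHNFVHPSDARYMKLHWVNLKWRQDYLCIVWQTL
>p3
FPVWWESCEHAQYWWWGNLHWCGKMGFQLRAKLTNAMEDGFLYCEYKQQDVLAIYFGQEKISNLQMCSQR
TGWLPGAMPLPRTRIEGLYSNSWDHHLLHWPLQMPDLECHYMMAGLKNPVRAMIPQC
>p4
GPDPSWSPPIPGGIFKLMAREHMLIDPYSIDKSMPHVHFYVHTTSIWVLRNDRSLCIAPHMMPFCRFQFT
VTVHPCNDYIYQAQVCFLNDVVVSAIWIYWCYWMRVILCETNYWHKWMMSTGMHMEPWATEMI
>p5
DPCEKMLQAAQYMKWFCKDNCSVTYIIWRGDAREKAMGYQKGNTMKVMWAMTTIMVAGCQFAVERHQLDH
FGFVKDDKPHLTCYTNGWLVALHCEYIRQTFTTFYGDQKNKQDEDHAFELNNNRKDWK
>p6
HNPTRRYDPWCFKVAEVFDLHQLLKHGYIFWYMTHLNEYAASFWTMAAVDFHGSPAWVLQLCSKTCRIDC
THMFADQGSLIKRCGCSKFTNYEGCDVTVMIHYAWSIEVLLWPNIGHH
>p7
FAWMCVLGENGTQAMYWFDPWVYQCAQHRGNYMLTLWLKIWHSISMLYVSIFVRCALKATPGNWAMSQWF
IWSNRHARIGMCAYFFMTTTWPVLDVLAMPQPHIEQFFWQWRSDCYHLPLLDYTVTLKIPIYFTKIWPAY
IGWPWFPQQY
>p8
NYIMQCQLCLDCLRWNVVMKIKIDILLCMLEYCLRWMSRMWNCFWMVYMLMPLTDQLCFNRGAPKQNVHS
NNGWVCIARVQEGWEAAGRVMALYKFGMFWGISTKLIIHQRNMLWVRR
>p9
WPYDLSPVAKMFQDFMQSFTGAFNVDPLSECNPARYNRSTTATLDTEMHLSHDVMFSPEWRIDKPFNELD
HGTYLYYYDVDRNRDYGLQMALDPFLSQAAMQAYDDTWWQAGGQTYYILEHERHISPTRAWISQMLRVCI
SFQHFNGTSWGFAYVWAGMN
>p10
DRQATDAPCPMGGHNAWPDIRFMPRQWDAPKTSTHFMHMFPFWTRCPNEHPRPSLASKDANHRHCQNVNM
KDKAQQNQNYSEPFEYAPKKPPQKCKRNWNRSNNIVMVPRHETEHFVPN
>p11
YQGCHQFIGDNWPSFFWINCAWNRAPCDAGKWDAFNGGQYPWCTRDDTEAIVTNCHYHGCDMGKDYCLNY
NLYETRNYNCGDNWTSQLIGRAHPFWTWAGWLRTNCCCEIFSWCFWLFPDSNEEERAVEILLCWDYCYWV
SPQRLF
>p12
CTHSEVKPAVWTENHCNHQTPITCFEIHIRWYMVNWDNKHCLGYNFYTYGCDNSMYKVHPLRNKQCAQPR
DWPTGGIWNKQGQVWKIPMQGAWIPMHNKRKMRMNQKMAIMNMCDRDKKYCGFTYKMDKKMCIYDTRSPD
PNRGTSDHCHQPIDHNYLWYYRVRQR
>p13
LLYGGKGHEADLCEICNNSNRLWMHDIHLWWDAYVDCSHADETFEGQQHCSETQPWFHMKMNECYSTVCD
KQQCYANPFHIIMDQAKHADAQ
>p14
AGNPFENEPMQVLCIHTQDCDDVFWVPSYQYCDRQLVIGIAEAPCHRYFFYAEQPEHYPRVRICFRWQVP
VFQLIAWRMGQYLYVKFVDAAKYHMFNVYTVADINLNYRVHHCN
>p15
WWNQRNNKCITARGFFPFQRHKWVYHMWNAKTWQENWKNLVHLGDQKTTNEIKHFHPVMSDAQRCEHDRH
YENKESEHINFQCLPHYPKPRGCQTYVRMMRGNLDQTMKYPQFGIKL
>p16
IACPKILPAPWLISTELKPWIIVQSSSPWEELFNEMPCTQGMALNPTIITTYCHPMSDHSMRYAVNFIYL
VTTAEKWTCNDSYNYWKCGVGPSWMIYWDNVICYRSNPRLNFRLRMPKQITHVYHDNGQERPH
>p17
YHCVMFMLSHRENFHFYYQALFIDMMFERSKEDAEMWEVDPEVTNRWVDKYYPAAHEWNNVKEPQPQTHH
HVNEFMPENTLSWINGGVAPIAEQTKAYGPDQFCVPMMNAKECM
>p18
ITIREWYTHRNFDSYYQRMMFMVLQHPEGSFKGNKLDGCWSRRNTCHISLDNMFYDKVNFQMDQSWA
>p19
HYCGFVHQEIAYIWYHLKHFRKDCCGWPWSMPKFDQMHTDRLQQQKFTAREVSHNSIKETLEMDTGMMPF
I
>p20
CFYCTSETYLATMSQSLQRHGNYLWDLKAQPPWWSDSHIHHHYLVEMQVRLCAMECCQYKRIAWKLSWVD
LEKPQYTVMNCEWTEELQKLMFKAIEMFDYCIRQVPDSYYKMLILQIDSYKSAQEHIFEKTTFMSMTPIP
LQFSQN
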