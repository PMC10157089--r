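# synthetic Eu(III) 5D0->7FJ emission spectrum (Gaussian bands, I_tot/I_MD = 27.46)
# wavelength_nm, intensity_au
570.0,1.59837e-06
570.5,4.77186e-06
571.0,1.3383e-05
571.5,3.52596e-05
572.0,8.72683e-05
572.5,0.000202905
573.0,0.000443185
573.5,0.000909356
574.0,0.00175283
574.5,0.00317397
575.0,0.0053991
575.5,0.00862773
576.0,0.0129518
576.5,0.0182649
577.0,0.0241971
577.5,0.0301137
578.0,0.0352065
578.5,0.0386668
579.0,0.0398942
579.5,0.0386668
580.0,0.0352065
580.5,0.0301137
581.0,0.0241971
581.5,0.0182649
582.0,0.0129518
582.5,0.00862794
583.0,0.00539984
583.5,0.00317648
584.0,0.00176082
584.5,0.000933216
585.0,0.0005101
585.5,0.000379203
586.0,0.00052361
586.5,0.00104978
587.0,0.00222931
587.5,0.00455155
588.0,0.00876575
588.5,0.0158703
589.0,0.0269956
589.5,0.0431387
590.0,0.0647588
590.5,0.0913245
591.0,0.120985
591.5,0.150569
592.0,0.176033
592.5,0.193334
593.0,0.199471
593.5,0.193334
594.0,0.176033
594.5,0.150569
595.0,0.120985
595.5,0.0913245
596.0,0.0647588
596.5,0.0431387
597.0,0.0269955
597.5,0.0158698
598.0,0.00876415
598.5,0.00454678
599.0,0.00221592
599.5,0.00101452
600.0,0.000436341
600.5,0.000176298
601.0,6.69183e-05
601.5,2.38751e-05
602.0,8.06478e-06
602.5,2.83146e-06
603.0,2.03573e-06
603.5,5.16059e-06
604.0,1.78945e-05
604.5,6.03673e-05
605.0,0.000191808
605.5,0.000572624
606.0,0.00160596
606.5,0.00423115
607.0,0.0104722
607.5,0.0243486
608.0,0.0531822
608.5,0.109123
609.0,0.21034
609.5,0.380876
610.0,0.647892
610.5,1.03533
611.0,1.55421
611.5,2.19179
612.0,2.90365
612.5,3.61365
613.0,4.22478
613.5,4.64002
614.0,4.78731
614.5,4.64002
615.0,4.22478
615.5,3.61365
616.0,2.90365
616.5,2.19179
617.0,1.55421
617.5,1.03533
618.0,0.647892
618.5,0.380876
619.0,0.21034
619.5,0.109123
620.0,0.0531822
620.5,0.0243486
621.0,0.0104722
621.5,0.00423115
622.0,0.00160596
622.5,0.000572624
623.0,0.000191805
623.5,6.03541e-05
624.0,1.78406e-05
624.5,4.95417e-06
625.0,1.29237e-06
625.5,3.16709e-07
626.0,7.29106e-08
626.5,1.5768e-08
627.0,3.20347e-09
627.5,6.11393e-10
628.0,1.09617e-10
628.5,1.84625e-11
629.0,2.92118e-12
629.5,4.34195e-13
630.0,6.06273e-14
630.5,7.95256e-15
631.0,9.79948e-16
631.5,1.13437e-16
632.0,1.23357e-17
632.5,1.26017e-18
633.0,1.20935e-19
633.5,1.09042e-20
634.0,9.42588e-22
634.5,3.006e-22
635.0,2.52497e-21
635.5,2.6254e-20
636.0,2.56994e-19
636.5,2.36328e-18
637.0,2.04156e-17
637.5,1.65678e-16
638.0,1.26307e-15
638.5,9.04574e-15
639.0,6.0858e-14
639.5,3.84634e-13
640.0,2.28368e-12
640.5,1.27373e-11
641.0,6.67389e-11
641.5,3.285e-10
642.0,1.51897e-09
642.5,6.59811e-09
643.0,2.69244e-08
643.5,1.03212e-07
644.0,3.7168e-07
644.5,1.25738e-06
645.0,3.99594e-06
645.5,1.19297e-05
646.0,3.34576e-05
646.5,8.81489e-05
647.0,0.000218171
647.5,0.000507262
648.0,0.00110796
648.5,0.00227339
649.0,0.00438208
649.5,0.00793491
650.0,0.0134977
650.5,0.0215693
651.0,0.0323794
651.5,0.0456623
652.0,0.0604927
652.5,0.0752844
653.0,0.0880163
653.5,0.096667
654.0,0.0997356
654.5,0.096667
655.0,0.0880163
655.5,0.0752844
656.0,0.0604927
656.5,0.0456623
657.0,0.0323794
657.5,0.0215693
658.0,0.0134977
658.5,0.00793491
659.0,0.00438208
659.5,0.00227339
660.0,0.00110796
660.5,0.000507262
661.0,0.000218171
661.5,8.81489e-05
662.0,3.34576e-05
662.5,1.19297e-05
663.0,3.99594e-06
663.5,1.25738e-06
664.0,3.7168e-07
664.5,1.03212e-07
665.0,2.69244e-08
665.5,6.59811e-09
666.0,1.51897e-09
666.5,3.285e-10
667.0,6.67389e-11
667.5,1.27373e-11
668.0,2.28368e-12
668.5,3.84634e-13
669.0,6.0858e-14
669.5,9.04574e-15
670.0,1.26307e-15
670.5,1.65678e-16
671.0,2.04156e-17
671.5,2.36328e-18
672.0,2.56994e-19
672.5,2.62536e-20
673.0,2.51948e-21
673.5,2.27138e-22
674.0,1.92365e-23
674.5,1.53045e-24
675.0,1.14384e-25
675.5,8.03104e-27
676.0,5.29705e-28
676.5,3.2822e-29
677.0,1.9293e-30
677.5,4.72169e-31
678.0,6.73002e-30
678.5,1.1553e-28
679.0,1.86456e-27
679.5,2.82693e-26
680.0,4.02633e-25
680.5,5.38717e-24
681.0,6.77125e-23
681.5,7.99527e-22
682.0,8.86858e-21
682.5,9.24128e-20
683.0,9.0462e-19
683.5,8.31873e-18
684.0,7.18629e-17
684.5,5.83188e-16
685.0,4.446e-15
685.5,3.1841e-14
686.0,2.1422e-13
686.5,1.35391e-12
687.0,8.03855e-12
687.5,4.48355e-11
688.0,2.34921e-10
688.5,1.15632e-09
689.0,5.34678e-09
689.5,2.32253e-08
690.0,9.47739e-08
690.5,3.63305e-07
691.0,1.30831e-06
691.5,4.42597e-06
692.0,1.40657e-05
692.5,4.19924e-05
693.0,0.000117771
693.5,0.000310284
694.0,0.000767961
694.5,0.00178556
695.0,0.00390003
695.5,0.00800234
696.0,0.0154249
696.5,0.0279309
697.0,0.0475121
697.5,0.075924
698.0,0.113975
698.5,0.160731
699.0,0.212934
699.5,0.265001
700.0,0.309817
700.5,0.340268
701.0,0.351069
701.5,0.340268
702.0,0.309817
702.5,0.265001
703.0,0.212934
703.5,0.160731
704.0,0.113975
704.5,0.075924
705.0,0.0475121
705.5,0.0279309
706.0,0.0154249
706.5,0.00800234
707.0,0.00390003
707.5,0.00178556
708.0,0.000767961
708.5,0.000310284
709.0,0.000117771
709.5,4.19924e-05
710.0,1.40657e-05
710.5,4.42597e-06
711.0,1.30831e-06
711.5,3.63305e-07
712.0,9.47739e-08
712.5,2.32253e-08
713.0,5.34678e-09
713.5,1.15632e-09
714.0,2.34921e-10
714.5,4.48355e-11
715.0,8.03855e-12
715.5,1.35391e-12
716.0,2.1422e-13
716.5,3.1841e-14
717.0,4.446e-15
717.5,5.83188e-16
718.0,7.18629e-17
718.5,8.31873e-18
719.0,9.0462e-19
719.5,9.24128e-20
720.0,8.86858e-21
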